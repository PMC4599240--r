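# Two-group differential expression (SAM statistic, permutation q-values),
# correlation screening against a target gene, and average-linkage Pearson
# clustering.  GSEA lives in gsea.R.

check_two_groups <- function(groups, min_n = 2L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two phenotype groups are required, got ",
         nlevels(groups))
  n <- table(groups)
  if (any(n == 0)) stop("one group is empty")
  if (any(n < min_n))
    stop("each group needs at least ", min_n, " samples")
  groups
}

# SAM ingredients for a genes x samples matrix and a two-level factor;
# d is computed as (mean of level 1) - (mean of level 2).
sam_stats <- function(mat, groups, s0) {
  ia <- groups == levels(groups)[1]
  ib <- !ia
  na <- sum(ia); nb <- sum(ib)
  ma <- rowMeans(mat[, ia, drop = FALSE])
  mb <- rowMeans(mat[, ib, drop = FALSE])
  ssa <- rowSums((mat[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((mat[, ib, drop = FALSE] - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * (ssa + ssb) / (na + nb - 2))
  if (is.null(s0)) s0 <- stats::median(s)
  list(d = (ma - mb) / (s + s0), s = s, s0 = s0, diff = ma - mb)
}

#' SAM-style two-group differential expression
#'
#' For each gene computes the moderated statistic
#' `d = (mean_A - mean_B) / (s + s0)` where `s` is the pooled standard error
#' of the group-mean difference and the exchangeability constant `s0` is the
#' median of all per-gene `s` (fixed from the observed data, also during
#' permutations).  Group A is the first factor level of `groups`.  False
#' discovery rates (q-values) are estimated from group-label permutations:
#' for each gene the expected number of null `|d|` values at least as large,
#' per permutation, is divided by the observed count, and the resulting FDR
#' curve is made monotone so that q is non-increasing in `|d|`.  The fold
#' change is `2^(mean_A - mean_B)` (expression is log2 scale) and a gene is
#' flagged significant iff `q < q_cut` and fold change `> fc_cut` or
#' `< 1/fc_cut`.
#'
#' @param mat genes x samples matrix of normalized log2 expression
#'   (no missing values -- an error, not imputation, if any are found).
#' @param groups two-level factor (or coercible) over the columns of `mat`.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param s0 optional fixed exchangeability constant (e.g. 0 to recover the
#'   plain t-like statistic in closed-form checks).
#' @param q_cut q-value significance threshold (default 0.01).
#' @param fc_cut linear fold-change threshold (default 2).
#' @return data frame `gene`, `d`, `fold_change`, `q`, `significant`,
#'   ordered as the input rows; attribute `s0` records the constant used.
#' @export
sam_differential <- function(mat, groups, n_perm = 1000L, seed = 1L,
                             s0 = NULL, q_cut = 0.01, fc_cut = 2) {
  if (any(is.na(mat)))
    stop("expression matrix contains missing values; imputation is refused")
  groups <- check_two_groups(groups)
  obs <- sam_stats(mat, groups, s0)
  absd <- abs(obs$d)
  m <- nrow(mat)
  set.seed(seed)
  # pooled null |d| across permutations
  null_absd <- numeric(0)
  null_list <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    gp <- sample(groups)
    null_list[[b]] <- abs(sam_stats(mat, gp, obs$s0)$d)
  }
  null_absd <- sort(unlist(null_list))
  n_null <- length(null_absd)
  # V_i: expected null count >= |d_i| per permutation; R_i: observed count
  V <- (n_null - findInterval(absd - 1e-12, null_absd)) / n_perm
  ord <- order(absd, decreasing = TRUE)
  R <- seq_len(m)                       # count of observed |d| >= threshold
  fdr <- pmin(1, V[ord] / R)
  q <- numeric(m)
  q[ord] <- rev(cummin(rev(fdr)))       # monotone non-increasing in |d|
  fc <- 2^obs$diff
  res <- data.frame(gene = rownames(mat), d = obs$d, fold_change = fc,
                    q = q,
                    significant = q < q_cut & (fc > fc_cut | fc < 1 / fc_cut),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "s0") <- obs$s0
  res
}

#' Correlation screening against a target gene
#'
#' Computes the Pearson correlation of every gene with a target gene across
#' a designated sample set and splits genes into a positively associated
#' list (r at least `cut`) and a negatively associated list (r at most
#' `-cut`).  The
#' target is excluded from its own lists.  Genes with zero variance over
#' the selected samples have no defined correlation and are excluded with a
#' warning.
#'
#' @param mat genes x samples log2 expression matrix.
#' @param target_gene row name of the target gene.
#' @param cut absolute correlation threshold, inclusive (default 0.5).
#' @param samples optional character vector restricting the sample set
#'   (e.g. the comparator cohort only); default all columns.
#' @return list with `positive`, `negative` (character vectors) and `r`
#'   (named vector of all defined correlations, target excluded).
#' @export
pcc_to_target <- function(mat, target_gene, cut = 0.5, samples = NULL) {
  if (!target_gene %in% rownames(mat))
    stop("target gene '", target_gene, "' not present in matrix")
  if (is.null(samples)) samples <- colnames(mat)
  sub <- mat[, samples, drop = FALSE]
  if (ncol(sub) < 3L) stop("at least 3 samples are required")
  tgt <- sub[target_gene, ]
  if (stats::sd(tgt) == 0) stop("target gene has zero variance")
  sds <- apply(sub, 1L, stats::sd)
  zv <- sds == 0
  if (any(zv))
    warning(sum(zv), " zero-variance gene(s) excluded from correlation")
  keep <- !zv & rownames(sub) != target_gene
  r <- as.vector(stats::cor(t(sub[keep, , drop = FALSE]), tgt))
  names(r) <- rownames(sub)[keep]
  list(positive = names(r)[r >= cut],
       negative = names(r)[r <= -cut],
       r = r)
}

#' Average-linkage hierarchical clustering on Pearson distance
#'
#' Clusters both rows (genes) and columns (samples) with distance
#' `1 - Pearson r` and pairwise average linkage.  A zero-variance row or
#' column makes the correlation undefined and is reported as an error naming
#' the offending feature.
#'
#' @param mat genes x samples matrix.
#' @param genes optional row subset to cluster.
#' @return list with `rows` and `cols`, each an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(mat, genes = NULL) {
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("at least 2 rows and 2 columns are required after subsetting")
  rsd <- apply(mat, 1L, stats::sd)
  if (any(rsd == 0))
    stop("zero-variance row: ", rownames(mat)[rsd == 0][1])
  csd <- apply(mat, 2L, stats::sd)
  if (any(csd == 0))
    stop("zero-variance column: ", colnames(mat)[csd == 0][1])
  dr <- stats::as.dist(1 - stats::cor(t(mat)))
  dc <- stats::as.dist(1 - stats::cor(mat))
  list(rows = stats::hclust(dr, method = "average"),
       cols = stats::hclust(dc, method = "average"))
}
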