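# Gene-set enrichment with phenotype permutation: signal-to-noise ranking,
# weighted Kolmogorov-Smirnov running sum (weight exponent 1), sign-matched
# nominal p, and an FDR from the pooled permutation ES distribution per sign.

# vectorized per-row SD
row_sd <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums(m * m) - n * mu^2, 0) / (n - 1))
}

# signal-to-noise ratio per gene for a two-level factor; level1 - level2
signal_to_noise <- function(mat, groups) {
  ia <- groups == levels(groups)[1]
  ib <- !ia
  ma <- rowMeans(mat[, ia, drop = FALSE])
  mb <- rowMeans(mat[, ib, drop = FALSE])
  sa <- row_sd(mat[, ia, drop = FALSE])
  sb <- row_sd(mat[, ib, drop = FALSE])
  (ma - mb) / pmax(sa + sb, 1e-8)
}

# weighted KS enrichment score for one set.
# stat: ranking statistic named by gene (any order); member: gene names.
gsea_es <- function(stat, member, weight = 1) {
  ord <- order(stat, decreasing = TRUE)
  r <- stat[ord]
  m <- names(r) %in% member
  nh <- sum(m)
  if (nh == 0L) return(NA_real_)
  n <- length(r)
  hitw <- abs(r)^weight * m
  denom <- sum(hitw)
  p_hit <- if (denom > 0) cumsum(hitw) / denom else cumsum(m) / nh
  p_miss <- if (n - nh > 0) cumsum(!m) / (n - nh) else rep(0, n)
  dev <- p_hit - p_miss
  unname(dev[which.max(abs(dev))])
}

#' Gene-set enrichment analysis with phenotype permutation
#'
#' Genes are ranked by the signal-to-noise ratio between the two phenotype
#' groups (first factor level minus second); each gene set's enrichment
#' score (ES) is the maximum-magnitude deviation of the weighted
#' Kolmogorov-Smirnov running sum (hit increments proportional to
#' `|statistic|^weight`, miss decrements uniform).  Significance comes from
#' phenotype permutation: the nominal p compares the observed ES against
#' same-sign permutation ES values of the same set, and the FDR compares,
#' per sign, against the ES distribution pooled over all sets and
#' permutations (no area normalization).  A set is flagged significant at
#' `fdr < fdr_cut` and `p < p_cut`.
#'
#' @param mat genes x samples log2 expression matrix.
#' @param groups two-level factor over the columns.
#' @param sets named list of gene-symbol vectors (see [read_gmt()]).
#' @param n_perm number of phenotype permutations (default 1000).
#' @param min_size minimum number of set members present in the matrix;
#'   smaller sets are skipped with a warning (default 50; configurable down
#'   to 1).
#' @param seed integer seed.
#' @param weight running-sum weight exponent (default 1).
#' @param fdr_cut,p_cut significance thresholds (defaults 0.20 and 0.05).
#' @return data frame `set`, `size`, `es`, `p`, `fdr`, `significant`.
#' @export
gsea_enrichment <- function(mat, groups, sets, n_perm = 1000L, min_size = 50L,
                            seed = 1L, weight = 1, fdr_cut = 0.20,
                            p_cut = 0.05) {
  groups <- check_two_groups(groups)
  present <- lapply(sets, intersect, x = rownames(mat))
  sizes <- lengths(present)
  skip <- sizes < max(1L, min_size)
  if (any(skip))
    warning("skipping ", sum(skip), " gene set(s) with fewer than ",
            min_size, " members present: ",
            paste(names(sets)[skip], collapse = ", "))
  sets <- sets[!skip]; present <- present[!skip]; sizes <- sizes[!skip]
  if (!length(sets))
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  stat <- signal_to_noise(mat, groups)
  names(stat) <- rownames(mat)
  es_obs <- vapply(present, function(g) gsea_es(stat, g, weight), numeric(1))
  set.seed(seed)
  es_null <- matrix(NA_real_, n_perm, length(sets))
  for (b in seq_len(n_perm)) {
    gp <- sample(groups)
    st <- signal_to_noise(mat, gp)
    names(st) <- rownames(mat)
    es_null[b, ] <- vapply(present, function(g) gsea_es(st, g, weight),
                           numeric(1))
  }
  p <- vapply(seq_along(sets), function(j) {
    nullj <- es_null[, j]
    if (es_obs[j] >= 0) {
      pos <- nullj[nullj >= 0]
      if (!length(pos)) return(0)
      mean(pos >= es_obs[j])
    } else {
      neg <- nullj[nullj < 0]
      if (!length(neg)) return(0)
      mean(neg <= es_obs[j])
    }
  }, numeric(1))
  pooled <- as.vector(es_null)
  fdr <- vapply(seq_along(sets), function(j) {
    e <- es_obs[j]
    if (e >= 0) {
      pp <- pooled[pooled >= 0]
      num <- if (length(pp)) mean(pp >= e) else 0
      den <- mean(es_obs[es_obs >= 0] >= e)
    } else {
      pp <- pooled[pooled < 0]
      num <- if (length(pp)) mean(pp <= e) else 0
      den <- mean(es_obs[es_obs < 0] <= e)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  data.frame(set = names(sets), size = as.integer(sizes), es = es_obs,
             p = p, fdr = fdr,
             significant = fdr < fdr_cut & p < p_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}
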