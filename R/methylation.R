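# Methylation-expression integration: probe-to-gene mapping, expression
# probeset selection, per-pair linear-model correlation with multiple-testing
# adjustment, candidate-gene selection, and bisulfite peak-ratio calls.

#' Map methylation probes to genes
#'
#' A probe is paired with a gene iff its position lies in the gene body or
#' within `flank` bp upstream or downstream of it, i.e. in
#' `[body start - flank, body end + flank]` (1-based inclusive, symmetric,
#' strand ignored).  A probe may pair with several genes.
#'
#' @param annot probe annotation data frame: `probe`, `chromosome`,
#'   `position` (1-based bp).
#' @param genes gene model data frame: `gene`, `chromosome`, `start`, `end`
#'   (1-based inclusive body coordinates, `start <= end`).
#' @param flank flanking distance in bp (default 10000).
#' @return data frame of pairs: `probe`, `gene`.
#' @export
map_probes_to_genes <- function(annot, genes, flank = 10000L) {
  require_columns(annot, c("probe", "chromosome", "position"),
                  "probe annotation")
  require_columns(genes, c("gene", "chromosome", "start", "end"),
                  "gene model table")
  if (any(genes$end < genes$start)) stop("gene model with end < start")
  out <- list()
  for (chr in intersect(unique(annot$chromosome), unique(genes$chromosome))) {
    pa <- annot[annot$chromosome == chr, , drop = FALSE]
    ga <- genes[genes$chromosome == chr, , drop = FALSE]
    probe_ir <- IRanges::IRanges(start = pa$position, width = 1L)
    gene_ir <- IRanges::IRanges(start = pmax(1L, ga$start - flank),
                                end = ga$end + flank)
    ov <- IRanges::findOverlaps(probe_ir, gene_ir)
    if (length(ov))
      out[[chr]] <- data.frame(probe = pa$probe[S4Vectors::queryHits(ov)],
                               gene = ga$gene[S4Vectors::subjectHits(ov)],
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(probe = character(0), gene = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse expression probesets to genes by highest mean expression
#'
#' For genes measured by several expression probesets, the probeset with the
#' highest mean expression across all samples represents the gene (ties go
#' to the first probeset in input order).  The selection is returned so the
#' choice is auditable.
#'
#' @param expr_probesets probesets x samples matrix.
#' @param map data frame `probeset`, `gene` (every gene >= 1 probeset).
#' @return list with `expr` (genes x samples matrix) and `selection`
#'   (data frame `gene`, `probeset`, `mean_expr`).
#' @export
pick_expression_probe <- function(expr_probesets, map) {
  require_columns(map, c("probeset", "gene"), "probeset map")
  miss <- setdiff(map$probeset, rownames(expr_probesets))
  if (length(miss))
    stop("probeset(s) absent from matrix: ", paste(head(miss, 3), collapse = ", "))
  rm_all <- rowMeans(expr_probesets)
  sel <- do.call(rbind, lapply(split(map$probeset, map$gene), function(ps) {
    i <- which.max(rm_all[ps])          # leftmost tie
    data.frame(probeset = ps[i], mean_expr = unname(rm_all[ps[i]]),
               stringsAsFactors = FALSE)
  }))
  sel <- data.frame(gene = rownames(sel), sel, row.names = NULL,
                    stringsAsFactors = FALSE)
  expr <- expr_probesets[sel$probeset, , drop = FALSE]
  rownames(expr) <- sel$gene
  list(expr = expr, selection = sel)
}

#' Correlate methylation with expression per probe-gene pair
#'
#' For every (probe, gene) pair, fits ordinary least squares of expression
#' on beta value across the shared samples (a Gaussian-identity generalized
#' linear model) and reports the slope t-statistic -- negative t means
#' methylation and expression are inversely related -- with a two-sided p
#' and a multiplicity-adjusted p (Benjamini-Hochberg by default) computed
#' across all tested pairs.  Probes missing beta in more than
#' `max_missing` of the shared samples are excluded up front; remaining
#' missing values are dropped pairwise.  Pairs with fewer than `min_n`
#' usable samples or zero variance in beta or expression are skipped with a
#' warning (the skip count is attached as attribute `n_skipped`).
#'
#' @param meth probes x samples beta matrix (values in \[0,1\], NA allowed).
#' @param expr genes x samples log2 expression matrix (no NA).
#' @param pairs data frame `probe`, `gene` (see [map_probes_to_genes()]).
#' @param adjust_method a [stats::p.adjust] method (default `"BH"`).
#' @param max_missing maximum tolerated fraction of missing beta per probe
#'   (default 0.2).
#' @param min_n minimum usable samples per pair (default 4).
#' @return data frame `probe`, `gene`, `n`, `slope`, `t`, `p`, `p_adj`.
#' @export
correlate_meth_expr <- function(meth, expr, pairs, adjust_method = "BH",
                                max_missing = 0.2, min_n = 4L) {
  require_columns(pairs, c("probe", "gene"), "pair list")
  shared <- intersect(colnames(meth), colnames(expr))
  if (length(shared) < min_n)
    stop("fewer than ", min_n, " shared samples between matrices")
  pairs <- pairs[pairs$probe %in% rownames(meth) &
                   pairs$gene %in% rownames(expr), , drop = FALSE]
  X <- meth[pairs$probe, shared, drop = FALSE]
  Y <- expr[pairs$gene, shared, drop = FALSE]
  miss_frac <- rowMeans(is.na(X))
  drop_missing <- miss_frac > max_missing
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  n <- rowSums(M)
  sx <- rowSums(X0)
  sy <- rowSums(Y * M)
  sxx <- rowSums(X0^2) - sx^2 / n
  syy <- rowSums(Y^2 * M) - sy^2 / n
  sxy <- rowSums(X0 * Y) - sx * sy / n
  tol <- 1e-12
  usable <- !drop_missing & n >= min_n & sxx > tol & syy > tol
  n_skipped <- sum(!usable)
  if (n_skipped)
    warning(n_skipped, " pair(s) skipped (excess missing beta, too few ",
            "samples, or zero variance)")
  slope <- se <- tstat <- p <- rep(NA_real_, nrow(pairs))
  i <- usable
  slope[i] <- sxy[i] / sxx[i]
  rss <- pmax(syy[i] - slope[i] * sxy[i], 0)
  se[i] <- sqrt(rss / (n[i] - 2) / sxx[i])
  tstat[i] <- ifelse(se[i] > 0, slope[i] / se[i],
                     sign(slope[i]) * Inf)
  p[i] <- 2 * stats::pt(-abs(tstat[i]), n[i] - 2)
  res <- data.frame(probe = pairs$probe, gene = pairs$gene,
                    n = as.integer(n), slope = slope, t = tstat, p = p,
                    p_adj = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  res$p_adj[i] <- stats::p.adjust(p[i], method = adjust_method)
  res <- res[i, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Select candidate silenced/activated genes
#'
#' Three-step selection mirroring the published screen:
#' (1) keep probe-gene pairs with a significant methylation-expression
#' correlation (`p_adj < p_cut`, or raw `p` when `use_adjusted = FALSE`;
#' both signs retained); (2) per kept probe, compute the mean and SD of beta
#' across the tumor-group samples; (3) emit genes with at least `min_probes`
#' kept probes whose mean is `> hi` or `< lo` and whose SD is `< sd_cut`.
#' Direction is `hyper` when the qualifying probe means are high, `hypo`
#' when low; a gene whose qualifying probes disagree is emitted with the
#' majority direction and a warning (ties resolve to `hyper`).
#'
#' @param results probe-gene correlation results (see
#'   [correlate_meth_expr()]).
#' @param meth probes x samples beta matrix.
#' @param groups named group factor (or character) over methylation samples.
#' @param tumor_group group level whose samples define the beta summaries
#'   (default: first level).  A different level, or all samples, may be
#'   supplied to average over the comparator or pooled cohort instead.
#' @param min_probes minimum qualifying probe count, inclusive (default 5).
#' @param hi,lo beta mean cuts, strict (defaults 0.75 and 0.25).
#' @param sd_cut beta SD cut, strict (default 0.25).
#' @param p_cut probe significance gate (default 0.05).
#' @param use_adjusted gate on adjusted p (default TRUE) or raw p.
#' @return data frame `gene`, `n_qualifying`, `direction`, `mean_beta`
#'   (mean over qualifying probe means), ordered by qualifying probe count
#'   then by summed `|t|`, both decreasing; attribute `probe_detail` holds
#'   the per-probe summaries of all kept probes.
#' @export
select_candidate_genes <- function(results, meth, groups, tumor_group = NULL,
                                   min_probes = 5L, hi = 0.75, lo = 0.25,
                                   sd_cut = 0.25, p_cut = 0.05,
                                   use_adjusted = TRUE) {
  groups <- as.factor(groups)
  if (is.null(names(groups)) && length(groups) == ncol(meth))
    names(groups) <- colnames(meth)
  if (is.null(tumor_group)) tumor_group <- levels(groups)[1]
  tum <- names(groups)[groups == tumor_group]
  tum <- intersect(tum, colnames(meth))
  if (!length(tum)) stop("no samples in tumor group '", tumor_group, "'")
  gate <- if (use_adjusted) results$p_adj else results$p
  kept <- results[!is.na(gate) & gate < p_cut, , drop = FALSE]
  if (!nrow(kept)) {
    out <- data.frame(gene = character(0), n_qualifying = integer(0),
                      direction = character(0), mean_beta = numeric(0))
    attr(out, "probe_detail") <- out
    return(out)
  }
  B <- meth[kept$probe, tum, drop = FALSE]
  mu <- rowMeans(B, na.rm = TRUE)
  sdv <- apply(B, 1L, stats::sd, na.rm = TRUE)
  detail <- data.frame(gene = kept$gene, probe = kept$probe,
                       mean_beta = unname(mu), sd_beta = unname(sdv),
                       t = kept$t,
                       qualifying = (mu > hi | mu < lo) & sdv < sd_cut,
                       direction = ifelse(mu > hi, "hyper",
                                          ifelse(mu < lo, "hypo", "mid")),
                       row.names = NULL, stringsAsFactors = FALSE)
  qual <- detail[detail$qualifying, , drop = FALSE]
  genes <- unique(qual$gene)
  rows <- lapply(genes, function(g) {
    q <- qual[qual$gene == g, , drop = FALSE]
    if (nrow(q) < min_probes) return(NULL)
    dirs <- q$direction
    if (length(unique(dirs)) > 1L) {
      warning("gene ", g, " has mixed-direction qualifying probes")
      direction <- if (sum(dirs == "hyper") >= sum(dirs == "hypo"))
        "hyper" else "hypo"
    } else direction <- dirs[1]
    data.frame(gene = g, n_qualifying = nrow(q), direction = direction,
               mean_beta = mean(q$mean_beta), abs_t = sum(abs(q$t)),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    out <- data.frame(gene = character(0), n_qualifying = integer(0),
                      direction = character(0), mean_beta = numeric(0))
  } else {
    rows <- rows[order(-rows$n_qualifying, -rows$abs_t), , drop = FALSE]
    out <- rows[, c("gene", "n_qualifying", "direction", "mean_beta")]
  }
  rownames(out) <- NULL
  attr(out, "probe_detail") <- detail
  out
}

#' Bisulfite peak-ratio methylation calls
#'
#' After bisulfite conversion, unmethylated cytosines read as thymine; the
#' methylation level of a CpG site is estimated as the cytosine peak height
#' over the sum of the cytosine and thymine peak heights.  Sites are
#' classified unmethylated (ratio in \[0, 0.20\]), partially methylated
#' ((0.20, 0.80\]) or fully methylated ((0.80, 1\]).
#'
#' @param sites data frame `site`, `c_peak`, `t_peak` (non-negative peak
#'   heights; both zero at a site is an error naming the site).
#' @param lo,hi class boundaries (defaults 0.20 and 0.80).
#' @return `sites` with added columns `ratio` and `class`.
#' @export
bisulfite_methylation_call <- function(sites, lo = 0.20, hi = 0.80) {
  require_columns(sites, c("site", "c_peak", "t_peak"), "bisulfite table")
  if (any(sites$c_peak < 0) || any(sites$t_peak < 0))
    stop("peak heights must be non-negative")
  zero <- sites$c_peak + sites$t_peak == 0
  if (any(zero))
    stop("site '", sites$site[zero][1], "': both peak heights are zero")
  ratio <- sites$c_peak / (sites$c_peak + sites$t_peak)
  sites$ratio <- ratio
  sites$class <- ifelse(ratio <= lo, "unmethylated",
                        ifelse(ratio <= hi, "partially_methylated",
                               "fully_methylated"))
  sites
}
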