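# Somatic/germline variant triage: the three-score filter cascade, RNA-seq
# expression verification, germline candidate rules, exact binomial
# recurrence testing and fusion-caller consensus.

require_columns <- function(df, cols, what = "variant table") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required field(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Somatic variant filter cascade
#'
#' Retains variants with `somatic_score >= -10`, `somatic_rank >= 0.1` and
#' `fet_score >= 13` (all thresholds inclusive).  The three scores are
#' platform-specific confidence fields treated as opaque numeric columns.
#' Per-stage drop counts are attached as attribute `stage_drops` and logged.
#'
#' @param variants data frame with numeric columns `somatic_score`,
#'   `somatic_rank`, `fet_score`.
#' @param cfg configuration list supplying the three thresholds
#'   (see [default_config()]).
#' @return the surviving rows, order preserved.
#' @export
somatic_filter_cascade <- function(variants, cfg = default_config()) {
  require_columns(variants, c("somatic_score", "somatic_rank", "fet_score"))
  bad <- !stats::complete.cases(variants[, c("somatic_score", "somatic_rank",
                                             "fet_score")])
  if (any(bad))
    stop("record ", which(bad)[1], " has missing score field(s): ",
         paste(c("somatic_score", "somatic_rank", "fet_score")[
       is.na(unlist(variants[which(bad)[1], c("somatic_score", "somatic_rank",
                                              "fet_score")]))],
       collapse = ", "))
  p1 <- variants$somatic_score >= cfg$somatic_score_min
  p2 <- variants$somatic_rank  >= cfg$somatic_rank_min
  p3 <- variants$fet_score     >= cfg$fet_score_min
  drops <- c(somatic_score = sum(!p1),
             somatic_rank  = sum(p1 & !p2),
             fet_score     = sum(p1 & p2 & !p3))
  message("filter cascade drops: ",
          paste(names(drops), drops, sep = "=", collapse = ", "))
  out <- variants[p1 & p2 & p3, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_drops") <- drops
  out
}

#' RNA-seq expression verification of variants
#'
#' A variant is flagged expressed iff its RNA-seq total coverage is at least
#' `min_cov` and its variant allele fraction (variant reads / total reads)
#' is at least `min_vaf`, both thresholds inclusive.  The VAF is computed
#' only when total reads are positive; zero coverage is never expressed and
#' never divides by zero.
#'
#' @param variants data frame with integer columns `rna_total_reads`,
#'   `rna_variant_reads` (`variant <= total`).
#' @param min_cov minimum total coverage (default 10).
#' @param min_vaf minimum variant allele fraction (default 0.2).
#' @return `variants` with added columns `vaf` (NA when total is 0) and
#'   logical `expressed`.
#' @export
rnaseq_verify <- function(variants, min_cov = 10L, min_vaf = 0.2) {
  require_columns(variants, c("rna_total_reads", "rna_variant_reads"))
  if (any(variants$rna_variant_reads > variants$rna_total_reads))
    stop("rna_variant_reads exceeds rna_total_reads")
  tot <- variants$rna_total_reads
  vaf <- ifelse(tot > 0, variants$rna_variant_reads / tot, NA_real_)
  variants$vaf <- vaf
  variants$expressed <- tot >= min_cov & !is.na(vaf) & vaf >= min_vaf
  variants
}

#' Germline candidate filter
#'
#' Retains germline variants in cancer-census genes that are predicted
#' damaging and are either absent from dbSNP or, if present, also recorded
#' as a somatic cancer mutation (the COSMIC rescue clause):
#' `gene_in_cosmic AND damaging_predicted AND (!in_dbsnp OR variant_in_cosmic)`.
#'
#' @param variants data frame with logical columns `gene_in_cosmic`,
#'   `damaging_predicted`, `in_dbsnp`, `variant_in_cosmic`.
#' @return the retained rows, order preserved.
#' @export
germline_candidate_filter <- function(variants) {
  require_columns(variants, c("gene_in_cosmic", "damaging_predicted",
                              "in_dbsnp", "variant_in_cosmic"))
  keep <- variants$gene_in_cosmic & variants$damaging_predicted &
    (!variants$in_dbsnp | variants$variant_in_cosmic)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact binomial recurrence test per gene
#'
#' For each gene, tests whether the observed mutation count exceeds what a
#' uniform background mutation rate predicts over the bases successfully
#' sequenced for that gene: the upper-tail probability
#' `P(X >= k)` with `X ~ Binomial(bases_sequenced, background_rate)`,
#' computed exactly.  A Bonferroni-adjusted p across tested genes is
#' emitted alongside the raw p.
#'
#' @param counts data frame with columns `gene`, `bases_sequenced` (> 0),
#'   `observed_mutations` (>= 0).
#' @param background_rate mutations per base, in (0,1).  A natural default
#'   is the cohort total mutation count divided by total bases.
#' @param alpha significance level used for the reported flag (default 0.05,
#'   applied to the raw p as in the published screen).
#' @return data frame `gene`, `bases_sequenced`, `observed_mutations`,
#'   `p`, `p_bonferroni`, `significant`.
#' @export
binomial_recurrence_test <- function(counts, background_rate, alpha = 0.05) {
  require_columns(counts, c("gene", "bases_sequenced", "observed_mutations"),
                  "mutation count table")
  if (!(background_rate > 0 && background_rate < 1))
    stop("background_rate must be in (0,1)")
  if (any(counts$bases_sequenced <= 0))
    stop("bases_sequenced must be > 0 for tested genes")
  if (any(counts$observed_mutations < 0))
    stop("observed_mutations must be >= 0")
  p <- stats::pbinom(counts$observed_mutations - 1, counts$bases_sequenced,
                     background_rate, lower.tail = FALSE)
  data.frame(gene = counts$gene,
             bases_sequenced = counts$bases_sequenced,
             observed_mutations = counts$observed_mutations,
             p = p,
             p_bonferroni = pmin(1, p * nrow(counts)),
             significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Fusion-caller consensus
#'
#' A fusion gene pair is consensus iff every caller reports it; pairs are
#' matched as unordered symbol pairs because callers disagree on 5'/3'
#' orientation reporting.  Breakpoints of the first caller (first level of
#' the `caller` column) are retained; the matching records of the other
#' callers are attached as attribute `evidence`.
#'
#' @param callsets data frame with columns `caller`, `gene_5prime`,
#'   `gene_3prime`, `chrom_5prime`, `pos_5prime`, `chrom_3prime`,
#'   `pos_3prime`, `supporting_reads`; at least 2 distinct callers.
#' @return consensus rows from the first caller, plus a column `n_callers`;
#'   attribute `evidence` holds the supporting records of the other callers.
#' @export
fusion_consensus <- function(callsets) {
  require_columns(callsets, c("caller", "gene_5prime", "gene_3prime"),
                  "fusion callset")
  callers <- unique(callsets$caller)
  if (length(callers) < 2L)
    stop("fusion consensus requires callsets from at least 2 callers")
  if (any(!nzchar(callsets$gene_5prime)) || any(!nzchar(callsets$gene_3prime)))
    stop("fusion gene symbols must be non-empty")
  key <- function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "|")
  callsets$.pair <- key(callsets$gene_5prime, callsets$gene_3prime)
  per_caller <- lapply(callers, function(cl)
    unique(callsets$.pair[callsets$caller == cl]))
  consensus <- Reduce(intersect, per_caller)
  first <- callsets[callsets$caller == callers[1] &
                      callsets$.pair %in% consensus, , drop = FALSE]
  first <- first[!duplicated(first$.pair), , drop = FALSE]
  first$n_callers <- rep(length(callers), nrow(first))
  evidence <- callsets[callsets$caller != callers[1] &
                         callsets$.pair %in% consensus, , drop = FALSE]
  first$.pair <- NULL
  evidence$.pair <- NULL
  rownames(first) <- NULL
  attr(first, "evidence") <- evidence
  first
}
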