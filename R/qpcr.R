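# Comparative-Ct relative quantitation with housekeeping normalization.

#' Relative quantitation by the comparative Ct method
#'
#' Replicate Ct values are averaged per (sample, target); an undetermined
#' well is an absent (NA) Ct, never an imputed cycle number.  For every
#' assay target: `dCt = Ct_target - Ct_housekeeping`,
#' `ddCt = dCt_sample - dCt_calibrator`, `RQ = 2^-ddCt` (amplification
#' efficiency fixed at 2).  The calibrator sample therefore has RQ exactly
#' 1.  A sample whose target Ct is undetermined in all replicates is flagged
#' `detectable = FALSE` with RQ reported as 0.  A sample without a
#' housekeeping Ct, or a calibrator without detectable target or
#' housekeeping signal, is an error.
#'
#' @param wells data frame `sample`, `target`, `ct` (NA = undetermined),
#'   `replicate`.
#' @param calibrator sample id used as calibrator (conventionally a single
#'   low-expression sample).
#' @param housekeeping name of the housekeeping target (default `"GAPDH"`).
#' @return data frame `sample`, `target`, `dct`, `ddct`, `rq`,
#'   `detectable`, one row per sample x assay target.
#' @export
relative_quantitation <- function(wells, calibrator, housekeeping = "GAPDH") {
  require_columns(wells, c("sample", "target", "ct"), "qPCR well table")
  if (any(!is.na(wells$ct) & wells$ct <= 0))
    stop("Ct values must be positive or undetermined (NA)")
  agg <- stats::aggregate(ct ~ sample + target, data = wells,
                          FUN = function(v) mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg$ct[is.nan(agg$ct)] <- NA_real_
  hk <- agg[agg$target == housekeeping, , drop = FALSE]
  targets <- setdiff(unique(agg$target), housekeeping)
  if (!length(targets)) stop("no assay target wells found")
  samples <- unique(agg$sample)
  no_hk <- setdiff(samples, hk$sample[!is.na(hk$ct)])
  if (length(no_hk))
    stop("sample '", no_hk[1], "' has no detectable housekeeping (",
         housekeeping, ") Ct")
  hk_ct <- stats::setNames(hk$ct, hk$sample)
  if (!calibrator %in% samples)
    stop("calibrator sample '", calibrator, "' not present")
  out <- list()
  for (tg in targets) {
    ta <- agg[agg$target == tg, , drop = FALSE]
    t_ct <- stats::setNames(ta$ct, ta$sample)
    cal_t <- t_ct[calibrator]
    if (is.na(cal_t))
      stop("calibrator sample '", calibrator,
           "' has undetermined Ct for target ", tg)
    dct_cal <- unname(cal_t - hk_ct[calibrator])
    dct <- unname(t_ct[samples] - hk_ct[samples])
    detectable <- !is.na(dct)
    ddct <- dct - dct_cal
    rq <- ifelse(detectable, 2^(-ddct), 0)
    out[[tg]] <- data.frame(sample = samples, target = tg,
                            dct = dct, ddct = ddct, rq = rq,
                            detectable = detectable,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
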