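#' Default pipeline configuration
#'
#' Returns the full set of pipeline thresholds as a named list.  The defaults
#' are the published operating point of the screen: segments are called from
#' at least 8 markers with |log2 ratio| > 0.5; somatic variants must have
#' somatic score >= -10, somatic rank >= 0.1 and FET score >= 13; RNA-seq
#' verification requires total coverage >= 10 and VAF >= 0.2; differential
#' expression is flagged at SAM q < 0.01 with fold change > 2 (or < 1/2);
#' correlation screening uses |PCC| >= 0.5; probe-gene correlations are gated
#' at adjusted p < 0.05; candidate genes need >= 5 probes with mean beta
#' above 0.75 or below 0.25 and SD < 0.25; bisulfite methylation classes split at
#' ratios 0.20 and 0.80; permutation procedures use 1000 permutations.
#'
#' @param seed integer seed recorded in every output header and used by all
#'   stochastic stages.
#' @param out_dir default output directory for pipeline commands.
#' @return named list of thresholds (a `RunConfig`).
#' @export
default_config <- function(seed = 1L, out_dir = "quiescreen_out") {
  list(
    # copy number
    min_markers      = 8L,
    log2_cut         = 0.5,
    cbs_alpha        = 0.01,
    cbs_min_width    = 2L,
    cbs_n_perm       = 1000L,
    autosomes_only   = TRUE,
    # variant cascade
    somatic_score_min = -10,
    somatic_rank_min  = 0.1,
    fet_score_min     = 13,
    min_coverage      = 10L,
    min_vaf           = 0.2,
    # expression
    sam_q_cut        = 0.01,
    fold_change_cut  = 2,
    n_perm           = 1000L,
    pcc_cut          = 0.5,
    gsea_min_size    = 50L,
    gsea_fdr_cut     = 0.20,
    gsea_p_cut       = 0.05,
    # methylation integration
    pair_p_cut       = 0.05,
    use_adjusted_p   = TRUE,
    adjust_method    = "BH",
    min_probes       = 5L,
    beta_hi          = 0.75,
    beta_lo          = 0.25,
    beta_sd_cut      = 0.25,
    # bisulfite calls
    bisulfite_lo     = 0.20,
    bisulfite_hi     = 0.80,
    # bookkeeping
    seed             = as.integer(seed),
    out_dir          = out_dir
  )
}

#' Read a flat key-value configuration file
#'
#' The configuration file is a flat YAML-style document: one `key: value`
#' pair per line, `#` comments and blank lines ignored.  Keys must be known
#' configuration names (see [default_config()]); values are coerced to the
#' type of the corresponding default.  Keys absent from the file keep their
#' defaults, so a config file containing only the thresholds being changed is
#' valid and reproducible.
#'
#' @param path path to the config file.
#' @param base configuration list to override (default [default_config()]).
#' @return the merged configuration list.
#' @export
read_config <- function(path, base = default_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("config parse error: expected 'key: value', got: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(base))
      stop("unknown configuration key: ", key)
    base[[key]] <- coerce_config_value(val, base[[key]])
  }
  base
}

coerce_config_value <- function(val, template) {
  if (is.logical(template)) {
    lv <- toupper(val) %in% c("TRUE", "YES", "1")
    if (!toupper(val) %in% c("TRUE", "YES", "1", "FALSE", "NO", "0"))
      stop("cannot interpret '", val, "' as logical")
    lv
  } else if (is.integer(template)) {
    as.integer(val)
  } else if (is.numeric(template)) {
    as.numeric(val)
  } else {
    val
  }
}

#' Write a configuration list as a flat key-value file
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v) paste(format(v, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = ","), character(1))
  writeLines(paste0(names(cfg), ": ", vals), path)
  invisible(path)
}

#' Stable digest of a configuration
#'
#' md5 of the canonical (sorted-key) textual form of the configuration.
#' Embedded in every output header so a result file identifies the exact
#' operating point that produced it.
#'
#' @param cfg configuration list.
#' @return md5 hex string.
#' @export
config_hash <- function(cfg) {
  o <- order(names(cfg))
  s <- paste(sprintf(
    "%s=%s", names(cfg)[o],
    vapply(cfg[o], function(v) paste(format(v, digits = 15, trim = TRUE,
                                            scientific = FALSE),
                                     collapse = ","), character(1))),
    collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

# one-line provenance header used by all tabular writers
provenance_header <- function(cfg, convention = NULL) {
  h <- sprintf("# quiescreen seed=%d config=%s", cfg$seed, config_hash(cfg))
  if (!is.null(convention)) h <- paste0(h, " coords=", convention)
  h
}
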