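# Synthetic cohort generator.  Emulates the statistical structure the screen
# assumes -- a small tumor cohort against a large comparator cohort, a
# near-quiescent copy-number genome with rare implanted segments, a driver
# gene silenced by promoter hypermethylation (beta 0.78 vs 0.14, expression
# fold change 0.05), a co-expressed gene module, and variant tables with
# pass/fail truth -- so every stage is testable without controlled-access
# data.  Every generator is a pure function of (spec, seed) and emits a
# truth table alongside the data.

#' Cohort specification for the synthetic generators
#'
#' Defaults are the published study design: 13 tumors vs 76 comparators for
#' expression, 11 of the 13 tumors with methylation, a driver gene whose
#' promoter probes have mean beta 0.78 in tumors vs 0.14 in comparators,
#' tumor/comparator expression fold change 0.05, and a co-regulated module
#' with pairwise correlation 0.7 to the driver.  Dispersions (beta SD 0.08,
#' expression SD 0.5) and the desk-scale feature counts are generator
#' choices documented in the methods vignette.
#'
#' @param n_tumor,n_comparator expression cohort sizes (13 / 76).
#' @param n_meth_tumor tumors with methylation data (11; must be <= n_tumor).
#' @param n_genes,n_probes feature counts (desk-scale defaults 1000 / 3000).
#' @param driver_promoter_probes promoter probes on the driver (6).
#' @param driver_beta_tumor,driver_beta_comparator promoter beta group means
#'   (0.78 / 0.14).
#' @param beta_sd per-probe beta SD across samples (0.08).
#' @param driver_fold_change tumor/comparator linear expression ratio (0.05).
#' @param module_size co-regulated genes correlated with the driver (50).
#' @param module_pcc target pairwise Pearson correlation, in (-1,1) (0.7).
#' @param expr_sd per-gene log2 expression SD (0.5).
#' @param background_beta bimodal background beta mixture: list with
#'   `means`, `sds` (per component) and `weight` of the first (low)
#'   component.
#' @param seed integer seed.
#' @return validated spec list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tumor = 13L, n_comparator = 76L, n_meth_tumor = 11L,
                        n_genes = 1000L, n_probes = 3000L,
                        driver_promoter_probes = 6L,
                        driver_beta_tumor = 0.78,
                        driver_beta_comparator = 0.14,
                        beta_sd = 0.08, driver_fold_change = 0.05,
                        module_size = 50L, module_pcc = 0.7,
                        expr_sd = 0.5,
                        background_beta = list(means = c(0.10, 0.85),
                                               sds = c(0.05, 0.05),
                                               weight = 0.5),
                        seed = 1L) {
  spec <- list(n_tumor = as.integer(n_tumor),
               n_comparator = as.integer(n_comparator),
               n_meth_tumor = as.integer(n_meth_tumor),
               n_genes = as.integer(n_genes),
               n_probes = as.integer(n_probes),
               driver_promoter_probes = as.integer(driver_promoter_probes),
               driver_beta_tumor = driver_beta_tumor,
               driver_beta_comparator = driver_beta_comparator,
               beta_sd = beta_sd,
               driver_fold_change = driver_fold_change,
               module_size = as.integer(module_size),
               module_pcc = module_pcc,
               expr_sd = expr_sd,
               background_beta = background_beta,
               seed = as.integer(seed))
  counts <- c("n_tumor", "n_comparator", "n_meth_tumor", "n_genes",
              "n_probes", "driver_promoter_probes", "module_size")
  for (f in counts)
    if (spec[[f]] < 1L) stop(f, " must be >= 1")
  if (spec$n_meth_tumor > spec$n_tumor)
    stop("n_meth_tumor cannot exceed n_tumor")
  for (f in c("driver_beta_tumor", "driver_beta_comparator"))
    if (spec[[f]] <= 0 || spec[[f]] >= 1) stop(f, " must be in (0,1)")
  if (spec$driver_fold_change <= 0) stop("driver_fold_change must be > 0")
  if (abs(spec$module_pcc) >= 1)
    stop("infeasible correlation target: |module_pcc| must be < 1")
  if (spec$beta_sd <= 0 || spec$expr_sd <= 0) stop("dispersions must be > 0")
  class(spec) <- "cohort_spec"
  spec
}

# exact truncated normal sampler (inverse-CDF; preserves the shape, no
# boundary point mass)
rtnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

cohort_sample_ids <- function(spec) {
  list(tumor = sprintf("TUM%02d", seq_len(spec$n_tumor)),
       comparator = sprintf("CMP%02d", seq_len(spec$n_comparator)))
}

#' Generate marker-level copy-number tracks with implanted segments
#'
#' Background log2 ratios are Normal(0, `sigma`) on an evenly spaced marker
#' grid per chromosome; each implant shifts a contiguous marker window of
#' one sample by its stated mean.  This emulates a near-quiescent genome
#' carrying a small number of true segmental gains or losses.
#'
#' @param spec a [cohort_spec()].
#' @param implants data frame of implants: `sample_id`, `chromosome`,
#'   `start_marker` (1-based index into the chromosome grid), `n_markers`
#'   (>= 1), `mean_log2`.  NULL or zero rows means no implants.
#' @param chromosomes chromosome names of the grid.
#' @param markers_per_chrom markers per chromosome.
#' @param spacing marker spacing in bp.
#' @param sigma background noise SD (default 0.1).
#' @return list with `tracks` (long data frame `sample_id`, `chromosome`,
#'   `position`, `log2` over all cohort samples) and `truth` (list with the
#'   implant table).
#' @export
gen_marker_track <- function(spec, implants = NULL,
                             chromosomes = paste0("chr", 1:4),
                             markers_per_chrom = 500L, spacing = 5000L,
                             sigma = 0.1) {
  ids <- cohort_sample_ids(spec)
  samples <- c(ids$tumor, ids$comparator)
  if (is.null(implants))
    implants <- data.frame(sample_id = character(0), chromosome = character(0),
                           start_marker = integer(0), n_markers = integer(0),
                           mean_log2 = numeric(0))
  if (nrow(implants)) {
    require_columns(implants, c("sample_id", "chromosome", "start_marker",
                                "n_markers", "mean_log2"), "implant table")
    if (any(!implants$chromosome %in% chromosomes))
      stop("implant on unknown chromosome")
    if (any(implants$n_markers < 1L)) stop("implant marker counts must be >= 1")
    if (any(implants$start_marker < 1L |
              implants$start_marker + implants$n_markers - 1L >
              markers_per_chrom))
      stop("implant exceeds chromosome length")
  }
  set.seed(spec$seed)
  pos <- spacing * seq_len(markers_per_chrom)
  n_chrom <- length(chromosomes)
  n_mark <- n_chrom * markers_per_chrom
  tracks <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    log2v <- stats::rnorm(n_mark, 0, sigma)
    df <- data.frame(sample_id = samples[si],
                     chromosome = rep(chromosomes, each = markers_per_chrom),
                     position = rep(pos, n_chrom),
                     log2 = log2v, stringsAsFactors = FALSE)
    imp <- implants[implants$sample_id == samples[si], , drop = FALSE]
    for (k in seq_len(nrow(imp))) {
      off <- (match(imp$chromosome[k], chromosomes) - 1L) * markers_per_chrom
      w <- off + seq.int(imp$start_marker[k],
                         imp$start_marker[k] + imp$n_markers[k] - 1L)
      df$log2[w] <- df$log2[w] + imp$mean_log2[k]
    }
    tracks[[si]] <- df
  }
  list(tracks = do.call(rbind, tracks),
       truth = list(implants = implants))
}

#' Generate a paired expression/methylation cohort with a silenced driver
#'
#' Builds an `OmicsCohort`: a genes x samples log2 expression matrix over
#' the full two-group design, a probes x samples beta matrix over the
#' methylation subset (`n_meth_tumor` tumors + all comparators), a
#' 450K-style probe annotation, and gene models.  The driver gene's
#' promoter probes are drawn from truncated normals with the stated group
#' means and SD; its expression differs between groups by
#' `log2(driver_fold_change)`.  Module genes share a latent factor with the
#' driver so their pairwise correlation with it is `module_pcc` (within
#' each group; the factor carries no group effect).  Background probes have
#' stable per-probe means drawn from the bimodal background mixture and are
#' independent of expression.  Promoter probes sit within 1500 bp of the
#' driver's transcription start; all other probes sit inside their gene's
#' body, and gene bodies are spaced so that each probe maps to exactly one
#' gene under the 10 kb flank rule.
#'
#' @param spec a [cohort_spec()] with `n_probes >= driver_promoter_probes + 10`.
#' @return list with `expr`, `expr_groups`, `meth`, `meth_groups`,
#'   `probe_annot`, `gene_models`, and `truth` (driver gene, module genes,
#'   promoter probes, generator parameters).
#' @export
gen_meth_expr <- function(spec) {
  if (spec$n_probes < spec$driver_promoter_probes + 10L)
    stop("n_probes must be at least driver_promoter_probes + 10")
  if (spec$module_size >= spec$n_genes)
    stop("module_size must be smaller than n_genes")
  set.seed(spec$seed)
  ids <- cohort_sample_ids(spec)
  expr_samples <- c(ids$tumor, ids$comparator)
  expr_groups <- factor(rep(c("tumor", "comparator"),
                            c(spec$n_tumor, spec$n_comparator)),
                        levels = c("tumor", "comparator"))
  names(expr_groups) <- expr_samples
  meth_samples <- c(ids$tumor[seq_len(spec$n_meth_tumor)], ids$comparator)
  meth_groups <- factor(rep(c("tumor", "comparator"),
                            c(spec$n_meth_tumor, spec$n_comparator)),
                        levels = c("tumor", "comparator"))
  names(meth_groups) <- meth_samples

  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  driver <- sample(genes, 1L)
  module <- sample(setdiff(genes, driver), spec$module_size)

  # gene models: bodies of 10 kb spaced 30 kb apart so +/-10 kb flanks of
  # neighbouring genes never overlap; round-robin over 4 chromosomes
  chroms <- paste0("chr", 1:4)
  chrom_of <- rep(chroms, length.out = spec$n_genes)
  idx_in_chrom <- stats::ave(seq_len(spec$n_genes), chrom_of,
                             FUN = seq_along)
  body_start <- 20001L + (idx_in_chrom - 1L) * 30000L
  gene_models <- data.frame(gene = genes, chromosome = chrom_of,
                            strand = "+", start = body_start,
                            end = body_start + 9999L,
                            stringsAsFactors = FALSE)

  # expression: background means U(4,12); driver shifted by log2(fc) in
  # tumors; module genes share a latent factor with the driver
  ns <- length(expr_samples)
  mu <- stats::runif(spec$n_genes, 4, 12)
  names(mu) <- genes
  expr <- matrix(stats::rnorm(spec$n_genes * ns, 0, spec$expr_sd),
                 spec$n_genes, ns, dimnames = list(genes, expr_samples))
  latent <- stats::rnorm(ns)
  rho <- spec$module_pcc
  # driver loads +sqrt(|rho|), module genes load sign(rho)*sqrt(|rho|), so
  # corr(driver, module gene) = rho; residual variance keeps total SD at
  # expr_sd
  load_d <- sqrt(abs(rho))
  load_m <- sign(rho) * load_d
  resid <- sqrt(1 - abs(rho))
  expr[driver, ] <- spec$expr_sd *
    (load_d * latent + resid * stats::rnorm(ns))
  for (g in module)
    expr[g, ] <- spec$expr_sd *
      (load_m * latent + resid * stats::rnorm(ns))
  expr <- expr + mu
  is_tum <- expr_groups == "tumor"
  expr[driver, is_tum] <- expr[driver, is_tum] + log2(spec$driver_fold_change)

  # probes: promoter probes on the driver near its TSS, remaining probes
  # inside gene bodies round-robin
  n_bg <- spec$n_probes - spec$driver_promoter_probes
  probes <- sprintf("cg%06d", seq_len(spec$n_probes))
  prom_probes <- probes[seq_len(spec$driver_promoter_probes)]
  bg_probes <- probes[-seq_len(spec$driver_promoter_probes)]
  drv_row <- match(driver, genes)
  tss <- gene_models$start[drv_row]
  prom_offsets <- round(seq(-1400, 400,
                            length.out = spec$driver_promoter_probes))
  bg_gene <- rep(genes, length.out = n_bg)
  bg_pos <- gene_models$start[match(bg_gene, genes)] +
    sample.int(10000L, n_bg, replace = TRUE) - 1L
  probe_annot <- data.frame(
    probe = probes,
    chromosome = c(rep(gene_models$chromosome[drv_row],
                       spec$driver_promoter_probes),
                   gene_models$chromosome[match(bg_gene, genes)]),
    position = c(tss + prom_offsets, bg_pos),
    cpg_relation = c(rep("island", spec$driver_promoter_probes),
                     sample(c("island", "shore", "shelf", "open_sea"),
                            n_bg, replace = TRUE,
                            prob = c(0.3, 0.2, 0.1, 0.4))),
    stringsAsFactors = FALSE)

  # methylation: promoter probes by group mean; background probes have a
  # stable bimodal per-probe mean, identical across groups
  nm <- length(meth_samples)
  is_mt <- meth_groups == "tumor"
  meth <- matrix(NA_real_, spec$n_probes, nm,
                 dimnames = list(probes, meth_samples))
  for (p in prom_probes) {
    meth[p, is_mt]  <- rtnorm(sum(is_mt), spec$driver_beta_tumor,
                              spec$beta_sd)
    meth[p, !is_mt] <- rtnorm(sum(!is_mt), spec$driver_beta_comparator,
                              spec$beta_sd)
  }
  bb <- spec$background_beta
  comp <- 1L + (stats::runif(n_bg) > bb$weight)
  bg_mean <- pmin(0.98, pmax(0.02, stats::rnorm(n_bg, bb$means[comp],
                                                bb$sds[comp])))
  for (j in seq_len(n_bg))
    meth[bg_probes[j], ] <- rtnorm(nm, bg_mean[j], spec$beta_sd)

  list(expr = expr, expr_groups = expr_groups,
       meth = meth, meth_groups = meth_groups,
       probe_annot = probe_annot, gene_models = gene_models,
       truth = list(driver = driver, module = module,
                    promoter_probes = prom_probes,
                    driver_beta_tumor = spec$driver_beta_tumor,
                    driver_beta_comparator = spec$driver_beta_comparator,
                    driver_fold_change = spec$driver_fold_change))
}

#' Generate a variant table with known filter truth
#'
#' Exactly `n_true_pass` records satisfy all three cascade thresholds
#' (somatic score >= -10, somatic rank >= 0.1, FET score >= 13) by
#' construction; each remaining record fails a non-empty subset of the
#' thresholds chosen uniformly.  RNA-seq read counts are generated so that a
#' recorded subset of the true survivors passes coverage/VAF verification
#' (by default the published 5/41 proportion).  Annotation flags for the
#' germline rules are drawn independently.
#'
#' @param spec a [cohort_spec()] (supplies thresholds' cohort context and
#'   the seed).
#' @param n_variants total records.
#' @param n_true_pass records passing the full cascade (<= n_variants).
#' @param n_expressed survivors passing RNA verification (default:
#'   `round(n_true_pass * 5 / 41)`).
#' @param cfg configuration supplying the thresholds.
#' @return list with `variants` (data frame of `VariantRecord` fields) and
#'   `truth` (per-variant pass/fail table).
#' @export
gen_variant_table <- function(spec, n_variants, n_true_pass,
                              n_expressed = round(n_true_pass * 5 / 41),
                              cfg = default_config()) {
  if (n_true_pass > n_variants)
    stop("n_true_pass cannot exceed n_variants")
  set.seed(spec$seed + 1L)
  empty <- data.frame(variant_id = character(0), sample_id = character(0),
                      chromosome = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), somatic_score = numeric(0),
                      somatic_rank = numeric(0), fet_score = numeric(0),
                      in_dbsnp = logical(0), variant_in_cosmic = logical(0),
                      gene_in_cosmic = logical(0),
                      damaging_predicted = logical(0),
                      rna_total_reads = integer(0),
                      rna_variant_reads = integer(0))
  if (n_variants == 0L)
    return(list(variants = empty,
                truth = data.frame(variant_id = character(0),
                                   pass_cascade = logical(0),
                                   expressed = logical(0))))
  ids <- cohort_sample_ids(spec)
  n <- n_variants
  pass <- c(rep(TRUE, n_true_pass), rep(FALSE, n - n_true_pass))
  score <- stats::runif(n, cfg$somatic_score_min, cfg$somatic_score_min + 60)
  rank <- stats::runif(n, cfg$somatic_rank_min, 1)
  fet <- stats::runif(n, cfg$fet_score_min, cfg$fet_score_min + 80)
  fail_idx <- which(!pass)
  for (i in fail_idx) {
    sub <- sample.int(7L, 1L)            # non-empty subset of 3 thresholds
    if (bitwAnd(sub, 1L)) score[i] <- stats::runif(1, -40, cfg$somatic_score_min - 1e-6)
    if (bitwAnd(sub, 2L)) rank[i] <- stats::runif(1, 0, cfg$somatic_rank_min - 1e-9)
    if (bitwAnd(sub, 4L)) fet[i] <- stats::runif(1, 0, cfg$fet_score_min - 1e-6)
  }
  expressed <- rep(FALSE, n)
  if (n_expressed > 0)
    expressed[sample(which(pass), min(n_expressed, n_true_pass))] <- TRUE
  tot <- integer(n); var_reads <- integer(n)
  for (i in seq_len(n)) {
    if (expressed[i]) {
      tot[i] <- sample(cfg$min_coverage:100, 1L)
      lo <- ceiling(cfg$min_vaf * tot[i])
      var_reads[i] <- sample(lo:tot[i], 1L)
    } else if (stats::runif(1) < 0.5) {
      tot[i] <- sample(0:(cfg$min_coverage - 1L), 1L)
      var_reads[i] <- if (tot[i] > 0) sample(0:tot[i], 1L) else 0L
    } else {
      tot[i] <- sample(cfg$min_coverage:100, 1L)
      hi <- max(0L, ceiling(cfg$min_vaf * tot[i]) - 1L)
      var_reads[i] <- sample(0:hi, 1L)
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  variants <- data.frame(
    variant_id = sprintf("var%05d", seq_len(n)),
    sample_id = sample(ids$tumor, n, replace = TRUE),
    chromosome = sample(paste0("chr", 1:4), n, replace = TRUE),
    position = sample.int(2e6L, n, replace = TRUE),
    ref = ref, alt = unname(alt),
    gene = sprintf("G%04d", sample.int(spec$n_genes, n, replace = TRUE)),
    somatic_score = score, somatic_rank = rank, fet_score = fet,
    in_dbsnp = stats::runif(n) < 0.3,
    variant_in_cosmic = stats::runif(n) < 0.1,
    gene_in_cosmic = stats::runif(n) < 0.5,
    damaging_predicted = stats::runif(n) < 0.4,
    rna_total_reads = tot, rna_variant_reads = var_reads,
    stringsAsFactors = FALSE)
  list(variants = variants,
       truth = data.frame(variant_id = variants$variant_id,
                          pass_cascade = pass, expressed = expressed,
                          stringsAsFactors = FALSE))
}

# default implant pattern mirroring the published quiescence contrast:
# most tumors carry at most one short segment (several carry none), while
# comparators typically carry one to three long, often arm-scale segments.
default_implants <- function(spec, markers_per_chrom = 500L,
                             chromosomes = paste0("chr", 1:4)) {
  ids <- cohort_sample_ids(spec)
  rows <- list()
  n_quiet <- min(5L, spec$n_tumor)       # tumors with no gains or losses
  tum_with <- ids$tumor[seq_len(spec$n_tumor) > n_quiet]
  for (s in tum_with) {
    nm <- sample(8:15, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, chromosome = sample(chromosomes, 1L),
      start_marker = sample.int(markers_per_chrom - nm, 1L),
      n_markers = nm, mean_log2 = sample(c(-0.8, 0.8), 1L),
      stringsAsFactors = FALSE)
  }
  for (s in ids$comparator[-1]) {        # one comparator stays quiescent
    for (k in seq_len(sample(1:3, 1L))) {
      nm <- sample(30:100, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, chromosome = sample(chromosomes, 1L),
        start_marker = sample.int(markers_per_chrom - nm, 1L),
        n_markers = nm, mean_log2 = sample(c(-0.9, 0.9), 1L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# qPCR plate emulating a low-expression assay target in tumors: comparators
# amplify ~9 cycles after the housekeeping gene, tumors ~14 or not at all.
gen_qpcr_table <- function(spec) {
  ids <- cohort_sample_ids(spec)
  samples <- c(ids$tumor, ids$comparator)
  is_tum <- samples %in% ids$tumor
  rows <- list()
  for (i in seq_along(samples)) {
    hk <- stats::rnorm(2, 20, 0.15)
    if (is_tum[i] && stats::runif(1) < 0.4) {
      tg <- c(NA_real_, NA_real_)        # undetectable
    } else {
      base <- if (is_tum[i]) 34 else 29
      tg <- stats::rnorm(2, base, 0.3)
    }
    rows[[i]] <- data.frame(sample = samples[i],
                            target = rep(c("GAPDH", "LNC1"), each = 2),
                            ct = c(hk, tg), replicate = c(1:2, 1:2),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# bisulfite peak heights at 4 CpG sites: tumors near-fully methylated,
# comparators unmethylated
gen_bisulfite_table <- function(spec) {
  ids <- cohort_sample_ids(spec)
  samples <- c(ids$tumor, ids$comparator[seq_len(min(7L, spec$n_comparator))])
  is_tum <- samples %in% ids$tumor
  rows <- list()
  for (i in seq_along(samples)) {
    r <- if (is_tum[i]) stats::runif(4, 0.82, 0.97) else
      stats::runif(4, 0.03, 0.18)
    h <- stats::runif(4, 200, 900)
    rows[[i]] <- data.frame(sample = samples[i],
                            site = paste0("CpG", 1:4),
                            c_peak = round(h * r, 1),
                            t_peak = round(h * (1 - r), 1),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic cohort bundle on disk
#'
#' Writes every input the screening pipeline consumes -- marker tracks,
#' variant TSV, expression/methylation matrices, phenotype labels (with
#' synthetic relapse labels on the tumors), probe annotation, gene models, a
#' GMT whose first set is the driver's co-expression module, a qPCR Ct
#' table, a bisulfite peak table -- plus the truth table as JSON and the
#' generating configuration.  The bundle is a pure function of
#' (spec, config): the same seed produces byte-identical files.  On any
#' failure the partially written bundle is removed.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created; must not collide with existing
#'   non-bundle content).
#' @param n_variants,n_true_pass variant-table parameters (defaults 1000 and
#'   41, the published survivor count used as a fixture parameter).
#' @param implants implant table, or `"default"` for the quiescence-contrast
#'   pattern described in [gen_marker_track()].
#' @param cfg configuration written alongside and embedded in headers.
#' @param markers_per_chrom markers per chromosome of the tracks.
#' @return `dir`, invisibly; see `truth.json` inside for the truth table.
#' @export
gen_cohort <- function(spec, dir, n_variants = 1000L, n_true_pass = 41L,
                       implants = "default", cfg = NULL,
                       markers_per_chrom = 500L) {
  if (is.null(cfg)) cfg <- default_config(seed = spec$seed)
  created <- !dir.exists(dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit({
    if (!ok && created) unlink(dir, recursive = TRUE)
  })
  set.seed(spec$seed + 2L)
  if (identical(implants, "default"))
    implants <- default_implants(spec, markers_per_chrom)
  mt <- gen_marker_track(spec, implants, markers_per_chrom = markers_per_chrom)
  me <- gen_meth_expr(spec)
  vt <- gen_variant_table(spec, n_variants, n_true_pass, cfg = cfg)
  set.seed(spec$seed + 3L)
  qp <- gen_qpcr_table(spec)
  bs <- gen_bisulfite_table(spec)

  write_tsv(mt$tracks, file.path(dir, "markers.tsv"), cfg)
  write_matrix_tsv(me$expr, file.path(dir, "expression.tsv"), "gene", cfg)
  write_matrix_tsv(me$meth, file.path(dir, "methylation.tsv"), "probe", cfg)
  ids <- cohort_sample_ids(spec)
  n_relapse <- min(6L, spec$n_tumor)
  pheno <- data.frame(sample = c(ids$tumor, ids$comparator),
                      group = rep(c("tumor", "comparator"),
                                  c(spec$n_tumor, spec$n_comparator)),
                      relapse = c(rep(c("relapse", "no_relapse"),
                                      c(n_relapse, spec$n_tumor - n_relapse)),
                                  rep(NA, spec$n_comparator)),
                      stringsAsFactors = FALSE)
  write_tsv(pheno, file.path(dir, "phenotype.tsv"), cfg)
  write_tsv(me$probe_annot, file.path(dir, "probe_annotation.tsv"), cfg)
  write_tsv(me$gene_models, file.path(dir, "gene_models.tsv"), cfg)
  sets <- list(DRIVER_MODULE = c(me$truth$driver, me$truth$module))
  all_genes <- rownames(me$expr)
  for (k in 1:3)
    sets[[sprintf("RANDOM_SET_%d", k)]] <-
      sample(all_genes, length(sets$DRIVER_MODULE))
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  write_tsv(vt$variants, file.path(dir, "variants.tsv"), cfg)
  write_tsv(qp, file.path(dir, "qpcr.tsv"), cfg)
  write_tsv(bs, file.path(dir, "bisulfite.tsv"), cfg)
  write_config(cfg, file.path(dir, "config.yaml"))
  truth <- list(driver = me$truth$driver, module = me$truth$module,
                promoter_probes = me$truth$promoter_probes,
                implants = mt$truth$implants,
                variant_truth = vt$truth,
                spec = unclass(spec)[setdiff(names(spec), "background_beta")])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  ok <- TRUE
  invisible(dir)
}
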