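# End-to-end screen over a cohort bundle: copy-number quiescence profiling,
# variant triage, differential expression and enrichment, methylation
# integration, bisulfite calls and qPCR quantitation, with a JSON report.

#' Run the full integrative screen on a cohort bundle
#'
#' Consumes a directory laid out as written by [gen_cohort()] (or assembled
#' by hand in the same dialects) and runs every stage whose inputs are
#' present:
#'
#' 1. segmentation of `markers.tsv` per sample, the 8-marker / |log2| > 0.5
#'    filter, and per-sample quiescence summaries;
#' 2. the somatic filter cascade, RNA-seq verification, germline candidate
#'    triage and binomial recurrence test on `variants.tsv`;
#' 3. fusion consensus on `fusions.tsv` (optional input);
#' 4. SAM differential expression tumor vs comparator, GSEA over
#'    `gene_sets.gmt`, a second SAM run over the synthetic relapse labels
#'    (its minimum q reported as the comparison's global p -- an interpretive
#'    choice, see the methods vignette), and average-linkage clustering of
#'    the top differential genes;
#' 5. probe-gene mapping, methylation-expression correlation, candidate-gene
#'    selection, and correlation screening of the top candidate;
#' 6. bisulfite peak-ratio calls and qPCR relative quantitation (calibrator:
#'    detectable sample with the highest delta-Ct, i.e. lowest expression).
#'
#' All tabular outputs carry a provenance header (seed + config hash);
#' `report.json` aggregates the headline counts.
#'
#' @param dir bundle directory.
#' @param cfg configuration (default: `config.yaml` inside the bundle if
#'   present, else [default_config()]).
#' @param out_dir output directory (default `<dir>/results`).
#' @return invisibly, a list with all intermediate results.
#' @export
screen_cohort <- function(dir, cfg = NULL, out_dir = file.path(dir, "results")) {
  if (is.null(cfg)) {
    cfg_path <- file.path(dir, "config.yaml")
    cfg <- if (file.exists(cfg_path)) read_config(cfg_path) else
      default_config()
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  pheno <- read_tsv(file.path(dir, "phenotype.tsv"))
  groups <- factor(pheno$group, levels = unique(pheno$group))
  names(groups) <- pheno$sample

  ## 1. copy number ---------------------------------------------------------
  markers_path <- file.path(dir, "markers.tsv")
  if (file.exists(markers_path)) {
    markers <- read_tsv(markers_path)
    samples <- unique(markers$sample_id)
    segs <- do.call(rbind, lapply(seq_along(samples), function(i) {
      segment_track(markers[markers$sample_id == samples[i], ],
                    sample_id = samples[i], alpha = cfg$cbs_alpha,
                    min_width = cfg$cbs_min_width, n_perm = cfg$cbs_n_perm,
                    seed = cfg$seed + i)
    }))
    filt <- filter_segments(segs, cfg$min_markers, cfg$log2_cut,
                            cfg$autosomes_only)
    qs <- quiescence_stats(filt, samples)
    names(filt)[names(filt) == "mean_log2"] <- "seg_mean"
    write_seg(filt, file.path(out_dir, "filtered_segments.seg"), cfg)
    write_tsv(qs, file.path(out_dir, "quiescence.tsv"), cfg)
    res$segments <- segs; res$filtered_segments <- filt; res$quiescence <- qs
  }

  ## 2. variants -------------------------------------------------------------
  var_path <- file.path(dir, "variants.tsv")
  if (file.exists(var_path)) {
    variants <- read_tsv(var_path)
    surv <- somatic_filter_cascade(variants, cfg)
    surv <- rnaseq_verify(surv, cfg$min_coverage, cfg$min_vaf)
    write_tsv(surv, file.path(out_dir, "variants_filtered.tsv"), cfg)
    germ <- germline_candidate_filter(variants)
    write_tsv(germ, file.path(out_dir, "germline_candidates.tsv"), cfg)
    # per-gene recurrence against an empirical background rate
    bases_per_gene <- 10000L   # nominal sequenced footprint per gene
    tab <- table(surv$gene)
    counts <- data.frame(gene = names(tab),
                         bases_sequenced = bases_per_gene,
                         observed_mutations = as.integer(tab),
                         stringsAsFactors = FALSE)
    if (nrow(counts)) {
      rate <- max(sum(counts$observed_mutations) /
                    (bases_per_gene * max(nrow(counts), 1L)), 1e-9)
      rec <- binomial_recurrence_test(counts, rate)
      write_tsv(rec, file.path(out_dir, "recurrence.tsv"), cfg)
      res$recurrence <- rec
    }
    res$variants_filtered <- surv
    res$germline_candidates <- germ
  }

  ## 3. fusions (optional) ---------------------------------------------------
  fus_path <- file.path(dir, "fusions.tsv")
  if (file.exists(fus_path)) {
    fus <- fusion_consensus(read_tsv(fus_path))
    write_tsv(fus, file.path(out_dir, "fusion_consensus.tsv"), cfg)
    res$fusions <- fus
  }

  ## 4. expression -----------------------------------------------------------
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  eg <- groups[colnames(expr)]
  sam <- sam_differential(expr, eg, n_perm = cfg$n_perm, seed = cfg$seed,
                          q_cut = cfg$sam_q_cut, fc_cut = cfg$fold_change_cut)
  write_tsv(sam, file.path(out_dir, "sam.tsv"), cfg)
  res$sam <- sam
  gmt_path <- file.path(dir, "gene_sets.gmt")
  if (file.exists(gmt_path)) {
    sets <- read_gmt(gmt_path)
    gsea <- gsea_enrichment(expr, eg, sets, n_perm = cfg$n_perm,
                            min_size = cfg$gsea_min_size, seed = cfg$seed,
                            fdr_cut = cfg$gsea_fdr_cut, p_cut = cfg$gsea_p_cut)
    write_tsv(gsea, file.path(out_dir, "gsea.tsv"), cfg)
    res$gsea <- gsea
  }
  if ("relapse" %in% names(pheno)) {
    rel <- pheno[!is.na(pheno$relapse), , drop = FALSE]
    if (length(unique(rel$relapse)) == 2L &&
          all(table(rel$relapse) >= 2L)) {
      rsam <- sam_differential(expr[, rel$sample, drop = FALSE],
                               factor(rel$relapse), n_perm = cfg$n_perm,
                               seed = cfg$seed + 7L, q_cut = cfg$sam_q_cut,
                               fc_cut = cfg$fold_change_cut)
      res$relapse_global_p <- min(rsam$q)
    }
  }
  top <- sam$gene[order(sam$q, -abs(sam$d))][seq_len(min(50L, nrow(sam)))]
  hc <- tryCatch(hierarchical_cluster(expr, top), error = function(e) NULL)
  if (!is.null(hc)) {
    write_newick(hc$rows, file.path(out_dir, "dendrogram_genes.nwk"))
    write_newick(hc$cols, file.path(out_dir, "dendrogram_samples.nwk"))
    res$clustering <- hc
  }

  ## 5. methylation integration ---------------------------------------------
  meth_path <- file.path(dir, "methylation.tsv")
  if (file.exists(meth_path)) {
    meth <- read_matrix_tsv(meth_path)
    annot <- read_tsv(file.path(dir, "probe_annotation.tsv"))
    gm <- read_tsv(file.path(dir, "gene_models.tsv"))
    pairs <- map_probes_to_genes(annot, gm)
    pg <- correlate_meth_expr(meth, expr, pairs,
                              adjust_method = cfg$adjust_method)
    write_tsv(pg, file.path(out_dir, "probe_gene_correlation.tsv"), cfg)
    mg <- groups[colnames(meth)]
    cand <- select_candidate_genes(pg, meth, mg,
                                   tumor_group = levels(groups)[1],
                                   min_probes = cfg$min_probes,
                                   hi = cfg$beta_hi, lo = cfg$beta_lo,
                                   sd_cut = cfg$beta_sd_cut,
                                   p_cut = cfg$pair_p_cut,
                                   use_adjusted = cfg$use_adjusted_p)
    write_tsv(cand, file.path(out_dir, "candidate_genes.tsv"), cfg)
    res$probe_gene <- pg
    res$candidates <- cand
    if (nrow(cand)) {
      comp <- names(eg)[eg == levels(groups)[2]]
      assoc <- tryCatch(
        pcc_to_target(expr, cand$gene[1], cut = cfg$pcc_cut, samples = comp),
        error = function(e) NULL)
      if (!is.null(assoc)) {
        write_tsv(data.frame(gene = names(assoc$r), r = unname(assoc$r)),
                  file.path(out_dir, "target_correlation.tsv"), cfg)
        res$target_correlation <- assoc
      }
    }
  }

  ## 6. assays ---------------------------------------------------------------
  bis_path <- file.path(dir, "bisulfite.tsv")
  if (file.exists(bis_path)) {
    calls <- bisulfite_methylation_call(read_tsv(bis_path),
                                        lo = cfg$bisulfite_lo,
                                        hi = cfg$bisulfite_hi)
    write_tsv(calls, file.path(out_dir, "bisulfite_calls.tsv"), cfg)
    res$bisulfite <- calls
  }
  qpcr_path <- file.path(dir, "qpcr.tsv")
  if (file.exists(qpcr_path)) {
    wells <- read_tsv(qpcr_path)
    targets <- setdiff(unique(wells$target), "GAPDH")
    agg <- stats::aggregate(ct ~ sample + target, data = wells,
                            FUN = function(v) mean(v, na.rm = TRUE),
                            na.action = stats::na.pass)
    ta <- agg[agg$target == targets[1] & !is.nan(agg$ct), , drop = FALSE]
    hk <- agg[agg$target == "GAPDH", , drop = FALSE]
    dct <- ta$ct - hk$ct[match(ta$sample, hk$sample)]
    calibrator <- ta$sample[which.max(dct)]
    rq <- relative_quantitation(wells, calibrator)
    write_tsv(rq, file.path(out_dir, "qpcr_rq.tsv"), cfg)
    res$qpcr <- rq
    res$qpcr_calibrator <- calibrator
  }

  ## report ------------------------------------------------------------------
  report <- list(
    n_samples = length(groups),
    groups = as.list(table(groups)),
    n_filtered_segments = if (!is.null(res$filtered_segments))
      nrow(res$filtered_segments) else NULL,
    n_variants_pass_cascade = if (!is.null(res$variants_filtered))
      nrow(res$variants_filtered) else NULL,
    n_variants_expressed = if (!is.null(res$variants_filtered))
      sum(res$variants_filtered$expressed) else NULL,
    n_significant_genes_sam = sum(sam$significant),
    n_significant_probe_gene_pairs = if (!is.null(res$probe_gene))
      sum(res$probe_gene$p_adj < cfg$pair_p_cut, na.rm = TRUE) else NULL,
    candidate_genes = if (!is.null(res$candidates))
      res$candidates$gene else NULL,
    relapse_global_p = res$relapse_global_p,
    qpcr_calibrator = res$qpcr_calibrator)
  report <- report[!vapply(report, is.null, logical(1))]
  write_json_report(report, file.path(out_dir, "report.json"), cfg)
  res$report <- report
  invisible(res)
}
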