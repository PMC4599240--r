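# Cohort generators: marker tracks, methylation/expression cohorts,
# variant tables, full bundles.

test_that("cohort_spec validates its invariants", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_tumor = 0), ">= 1")
  expect_error(cohort_spec(driver_beta_tumor = 1.2), "in \\(0,1\\)")
  expect_error(cohort_spec(driver_fold_change = 0), "> 0")
  expect_error(cohort_spec(module_pcc = 1), "infeasible")
  expect_error(cohort_spec(n_meth_tumor = 20, n_tumor = 13), "exceed")
})

test_that("null marker tracks average to zero at large n", {
  spec <- cohort_spec(n_tumor = 1L, n_comparator = 1L, n_meth_tumor = 1L, seed = 1L)
  mt <- gen_marker_track(spec, implants = NULL,
                         chromosomes = c("chr1", "chr2"),
                         markers_per_chrom = 25000L, sigma = 0.1)
  one <- mt$tracks[mt$tracks$sample_id == "TUM01", ]
  expect_equal(nrow(one), 50000L)
  expect_gt(mean(one$log2), -0.02)
  expect_lt(mean(one$log2), 0.02)
  expect_equal(nrow(mt$truth$implants), 0L)      # no-op implant
})

test_that("implants are validated and recovered by segmentation + filter", {
  spec <- cohort_spec(n_tumor = 1L, n_comparator = 1L, n_meth_tumor = 1L, seed = 3L)
  bad <- data.frame(sample_id = "TUM01", chromosome = "chr1",
                    start_marker = 195L, n_markers = 12L, mean_log2 = 0.8)
  expect_error(gen_marker_track(spec, bad, markers_per_chrom = 200L),
               "exceeds chromosome length")
  imp <- data.frame(sample_id = "TUM01", chromosome = "chr1",
                    start_marker = 100L, n_markers = 12L, mean_log2 = 0.8)
  mt <- gen_marker_track(spec, imp, chromosomes = "chr1",
                         markers_per_chrom = 200L, sigma = 0.1)
  tr <- mt$tracks[mt$tracks$sample_id == "TUM01", ]
  segs <- segment_track(tr[, c("chromosome", "position", "log2")],
                        sample_id = "TUM01", n_perm = 500L, seed = 1L)
  filt <- filter_segments(segs)
  expect_equal(nrow(filt), 1L)
  expect_equal(filt$call, "gain")
  # recovered window overlaps the implanted one
  imp_start <- tr$position[100] - 1L
  imp_end <- tr$position[111]
  expect_lt(filt$start, imp_end)
  expect_gt(filt$end, imp_start)
})

test_that("gen_meth_expr emits the published cohort shapes", {
  spec <- cohort_spec(n_genes = 200L, n_probes = 400L, seed = 5L)
  cohort <- gen_meth_expr(spec)
  expect_equal(dim(cohort$expr), c(200L, 13L + 76L))
  expect_equal(dim(cohort$meth), c(400L, 11L + 76L))
  expect_equal(unname(table(cohort$expr_groups)), c(13L, 76L),
               ignore_attr = TRUE)
  expect_equal(unname(table(cohort$meth_groups)), c(11L, 76L),
               ignore_attr = TRUE)
  # invariants: beta in [0,1], expression finite
  expect_true(all(cohort$meth >= 0 & cohort$meth <= 1))
  expect_true(all(is.finite(cohort$expr)))
  # promoter probes within 1500 bp of the driver TSS
  drv <- cohort$truth$driver
  tss <- cohort$gene_models$start[cohort$gene_models$gene == drv]
  pp <- cohort$probe_annot[cohort$probe_annot$probe %in%
                             cohort$truth$promoter_probes, ]
  expect_true(all(abs(pp$position - tss) <= 1500))
  # pure function of (spec, seed)
  again <- gen_meth_expr(cohort_spec(n_genes = 200L, n_probes = 400L,
                                     seed = 5L))
  expect_identical(cohort, again)
  expect_error(gen_meth_expr(cohort_spec(n_probes = 10L, n_genes = 50L)),
               "driver_promoter_probes")
})

test_that("driver promoter beta and module correlation match the spec", {
  means <- replicate(25, {
    spec <- cohort_spec(n_genes = 120L, n_probes = 200L, module_size = 15L,
                        seed = sample.int(1e6, 1))
    cohort <- gen_meth_expr(spec)
    tum <- names(cohort$meth_groups)[cohort$meth_groups == "tumor"]
    mean(cohort$meth[cohort$truth$promoter_probes, tum])
  })
  expect_lt(abs(mean(means) - 0.78), 0.03)

  # module genes correlate with the driver at the target level
  spec <- cohort_spec(n_genes = 300L, n_comparator = 500L, module_size = 20L,
                      seed = 6L)
  cohort <- gen_meth_expr(spec)
  comp <- names(cohort$expr_groups)[cohort$expr_groups == "comparator"]
  r <- sapply(cohort$truth$module, function(g)
    cor(cohort$expr[g, comp], cohort$expr[cohort$truth$driver, comp]))
  expect_lt(abs(mean(r) - 0.7), 3 * sd(r) / sqrt(length(r)) + 0.05)

  # group means converge to spec parameters at large n (3 SE tolerance)
  tum_b <- cohort$meth[cohort$truth$promoter_probes,
                       names(cohort$meth_groups)[cohort$meth_groups == "tumor"]]
  cmp_b <- cohort$meth[cohort$truth$promoter_probes,
                       names(cohort$meth_groups)[cohort$meth_groups == "comparator"]]
  expect_lt(abs(mean(cmp_b) - 0.14), 3 * sd(cmp_b) / sqrt(length(cmp_b)) + 0.01)
  expect_lt(abs(mean(tum_b) - 0.78), 3 * sd(tum_b) / sqrt(length(tum_b)) + 0.01)
})

test_that("variant generator honours truth-by-construction", {
  spec <- tiny_spec(seed = 19)
  expect_equal(nrow(gen_variant_table(spec, 0L, 0L)$variants), 0L)
  vt <- gen_variant_table(spec, 1000L, 41L)
  surv <- suppressMessages(somatic_filter_cascade(vt$variants))
  expect_equal(nrow(surv), 41L)
  expect_setequal(surv$variant_id,
                  vt$truth$variant_id[vt$truth$pass_cascade])
  # recorded expressed subset passes RNA verification
  ver <- rnaseq_verify(surv)
  expect_setequal(ver$variant_id[ver$expressed],
                  vt$truth$variant_id[vt$truth$expressed])
  expect_error(gen_variant_table(spec, 10L, 11L), "exceed")
})

test_that("records at the exact thresholds all pass the cascade", {
  v <- data.frame(somatic_score = rep(-10, 5), somatic_rank = rep(0.1, 5),
                  fet_score = rep(13, 5))
  expect_equal(nrow(suppressMessages(somatic_filter_cascade(v))), 5L)
})

test_that("bundles are deterministic and feed the screen end to end", {
  spec <- tiny_spec(seed = 23)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_cohort(spec, file.path(d1, "b"), n_variants = 150L, n_true_pass = 15L,
             markers_per_chrom = 100L)
  gen_cohort(spec, file.path(d2, "b"), n_variants = 150L, n_true_pass = 15L,
             markers_per_chrom = 100L)
  files <- list.files(file.path(d1, "b"))
  expect_true(all(c("markers.tsv", "expression.tsv", "methylation.tsv",
                    "phenotype.tsv", "probe_annotation.tsv",
                    "gene_models.tsv", "gene_sets.gmt", "variants.tsv",
                    "qpcr.tsv", "bisulfite.tsv", "truth.json",
                    "config.yaml") %in% files))
  for (f in files)
    expect_identical(readLines(file.path(d1, "b", f)),
                     readLines(file.path(d2, "b", f)), label = f)
})

test_that("a failed bundle write removes the incomplete directory", {
  spec <- tiny_spec(seed = 29)
  root <- withr::local_tempdir()
  target <- file.path(root, "bundle")
  bad_implants <- data.frame(sample_id = "TUM01", chromosome = "chrZZ",
                             start_marker = 1L, n_markers = 5L,
                             mean_log2 = 1)
  expect_error(gen_cohort(spec, target, implants = bad_implants,
                          markers_per_chrom = 100L))
  expect_false(dir.exists(target))
})
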