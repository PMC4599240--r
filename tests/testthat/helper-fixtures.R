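# Shared fixture builders.  Everything is generated in code at test time;
# no binary or stored fixtures.

# small cohort spec for fast module tests
tiny_spec <- function(seed = 1L, ...) {
  cohort_spec(n_tumor = 4L, n_comparator = 8L, n_meth_tumor = 3L,
              n_genes = 60L, n_probes = 120L, module_size = 10L,
              seed = seed, ...)
}

# random segment table for filter oracles
random_segments <- function(n, seed = 1L) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%02d", sample.int(10, n, replace = TRUE)),
    chromosome = sample(c(paste0("chr", 1:5), "chrX"), n, replace = TRUE),
    start = as.integer(sample.int(1e6, n)),
    end = NA_integer_,
    n_markers = sample.int(20, n, replace = TRUE),
    mean_log2 = round(runif(n, -1.2, 1.2), 3),
    call = "neutral", stringsAsFactors = FALSE) |>
    transform(end = start + as.integer(sample.int(1e5, n)))
}

# random variant table for cascade/verification/germline oracles;
# scores concentrated near the thresholds so boundaries get exercised
random_variants <- function(n, seed = 1L) {
  set.seed(seed)
  tot <- sample(0:30, n, replace = TRUE)
  data.frame(
    variant_id = sprintf("v%04d", seq_len(n)),
    gene = sprintf("G%03d", sample.int(50, n, replace = TRUE)),
    somatic_score = round(runif(n, -20, 0), 2),
    somatic_rank = round(runif(n, 0, 0.3), 3),
    fet_score = round(runif(n, 5, 20), 2),
    in_dbsnp = runif(n) < 0.5,
    variant_in_cosmic = runif(n) < 0.3,
    gene_in_cosmic = runif(n) < 0.5,
    damaging_predicted = runif(n) < 0.5,
    rna_total_reads = tot,
    rna_variant_reads = vapply(tot, function(t)
      if (t > 0) sample(0:t, 1L) else 0L, integer(1)),
    stringsAsFactors = FALSE)
}

# random fusion callsets
random_callsets <- function(n_per_caller, n_callers = 2L, n_genes = 12L,
                            seed = 1L) {
  set.seed(seed)
  gs <- sprintf("FG%02d", seq_len(n_genes))
  do.call(rbind, lapply(seq_len(n_callers), function(cl) {
    g5 <- sample(gs, n_per_caller, replace = TRUE)
    g3 <- vapply(g5, function(g) sample(setdiff(gs, g), 1L), character(1))
    data.frame(caller = paste0("caller", cl), gene_5prime = g5,
               gene_3prime = unname(g3),
               chrom_5prime = "chr1", pos_5prime = seq_len(n_per_caller),
               chrom_3prime = "chr2", pos_3prime = seq_len(n_per_caller),
               supporting_reads = sample.int(50, n_per_caller, TRUE),
               stringsAsFactors = FALSE)
  }))
}

# expression matrix with two groups and no signal (null)
null_expr <- function(n_genes, n_a, n_b, seed = 1L, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_a + n_b), 0, sd), n_genes,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_a + n_b))))
  groups <- factor(rep(c("A", "B"), c(n_a, n_b)), levels = c("A", "B"))
  names(groups) <- colnames(m)
  list(mat = m, groups = groups)
}

# qPCR wells with exact Ct values (2 replicates, no noise)
make_wells <- function(samples, target_ct, hk_ct, target = "TGT") {
  do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(sample = samples[i],
               target = rep(c("GAPDH", target), each = 2),
               ct = c(hk_ct[i], hk_ct[i], target_ct[i], target_ct[i]),
               replicate = c(1:2, 1:2), stringsAsFactors = FALSE)
  }))
}

# independent brute-force re-evaluation of the candidate-gene selection
oracle_select <- function(results, meth, tum_samples, min_probes = 5L,
                          hi = 0.75, lo = 0.25, sd_cut = 0.25,
                          p_cut = 0.05) {
  kept <- results[!is.na(results$p_adj) & results$p_adj < p_cut, ,
                  drop = FALSE]
  out <- character(0)
  for (g in unique(kept$gene)) {
    sub <- kept[kept$gene == g, , drop = FALSE]
    nq <- 0L
    for (i in seq_len(nrow(sub))) {
      b <- meth[sub$probe[i], tum_samples]
      m <- mean(b, na.rm = TRUE); s <- sd(b, na.rm = TRUE)
      if ((m > hi || m < lo) && s < sd_cut) nq <- nq + 1L
    }
    if (nq >= min_probes) out <- c(out, g)
  }
  sort(out)
}
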