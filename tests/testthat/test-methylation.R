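# Probe-gene mapping, probeset selection, methylation-expression
# correlation, candidate selection, bisulfite calls.

test_that("probe-gene mapping honours the 10 kb flank boundary", {
  genes <- data.frame(gene = "GX", chromosome = "chr1",
                      start = 50000L, end = 60000L)
  annot <- data.frame(probe = c("p_in", "p_9999", "p_10000", "p_10001",
                                "p_down_ok", "p_down_far"),
                      chromosome = "chr1",
                      position = c(55000L,          # inside body
                                   50000L - 9999L,  # paired
                                   50000L - 10000L, # boundary: paired
                                   50000L - 10001L, # not paired
                                   60000L + 10000L, # paired
                                   60000L + 10001L))
  pairs <- map_probes_to_genes(annot, genes)
  expect_setequal(pairs$probe, c("p_in", "p_9999", "p_10000", "p_down_ok"))
})

test_that("probe-gene mapping equals a brute-force interval scan", {
  set.seed(12)
  genes <- data.frame(gene = sprintf("G%02d", 1:30),
                      chromosome = sample(c("chr1", "chr2"), 30, TRUE),
                      start = sample.int(5e5, 30), end = NA_integer_)
  genes$end <- genes$start + sample.int(3e4, 30)
  annot <- data.frame(probe = sprintf("cg%03d", 1:300),
                      chromosome = sample(c("chr1", "chr2"), 300, TRUE),
                      position = sample.int(6e5, 300))
  pairs <- map_probes_to_genes(annot, genes)
  oracle <- list()
  for (i in seq_len(nrow(annot))) for (j in seq_len(nrow(genes))) {
    if (annot$chromosome[i] == genes$chromosome[j] &&
          annot$position[i] >= genes$start[j] - 10000 &&
          annot$position[i] <= genes$end[j] + 10000)
      oracle[[length(oracle) + 1L]] <- paste(annot$probe[i], genes$gene[j])
  }
  expect_setequal(paste(pairs$probe, pairs$gene), unlist(oracle))
})

test_that("probeset selection takes the highest-mean probeset", {
  m <- rbind(ps1 = c(5, 5, 5), ps2 = c(7, 7, 7), ps3 = c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  map <- data.frame(probeset = c("ps1", "ps2", "ps3"),
                    gene = c("GA", "GA", "GB"))
  out <- pick_expression_probe(m, map)
  expect_equal(out$selection$probeset[out$selection$gene == "GA"], "ps2")
  expect_equal(out$expr["GA", ], m["ps2", ])
  expect_equal(out$selection$probeset[out$selection$gene == "GB"], "ps3")
  # random argmax oracle
  set.seed(13)
  m2 <- matrix(rnorm(200), 40, 5,
               dimnames = list(sprintf("p%02d", 1:40), paste0("s", 1:5)))
  map2 <- data.frame(probeset = rownames(m2),
                     gene = sprintf("g%02d", sample.int(12, 40, TRUE)))
  out2 <- pick_expression_probe(m2, map2)
  for (g in unique(map2$gene)) {
    ps <- map2$probeset[map2$gene == g]
    expect_equal(out2$selection$probeset[out2$selection$gene == g],
                 ps[which.max(rowMeans(m2[ps, , drop = FALSE]))])
  }
})

test_that("regression t equals the correlation closed form", {
  set.seed(14)
  n <- 20
  meth <- matrix(runif(200 * n), 200, n,
                 dimnames = list(sprintf("cg%03d", 1:200),
                                 sprintf("s%02d", 1:n)))
  expr <- matrix(rnorm(200 * n), 200, n,
                 dimnames = list(sprintf("g%03d", 1:200), colnames(meth)))
  pairs <- data.frame(probe = rownames(meth), gene = rownames(expr))
  res <- correlate_meth_expr(meth, expr, pairs)
  r <- sapply(seq_len(200), function(i) cor(meth[i, ], expr[i, ]))
  t_oracle <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  # BH preserves p-value order
  o <- order(res$p)
  expect_true(all(diff(res$p_adj[o]) >= -1e-12))
  expect_true(all(res$p_adj >= res$p - 1e-12))
})

test_that("perfect inverse relation gives negative t and p of zero", {
  n <- 10
  e <- seq(1, 5, length.out = n)
  b <- 0.9 - 0.15 * e                    # exact negative linear transform
  meth <- matrix(b, 1, n, dimnames = list("cg1", paste0("s", 1:n)))
  expr <- matrix(e, 1, n, dimnames = list("g1", paste0("s", 1:n)))
  res <- correlate_meth_expr(meth, expr, data.frame(probe = "cg1", gene = "g1"))
  expect_lt(res$t, 0)
  expect_equal(res$p, 0)
})

test_that("correlation results are invariant to sample order; skips warn", {
  set.seed(15)
  n <- 15
  meth <- matrix(runif(50 * n), 50, n,
                 dimnames = list(sprintf("cg%02d", 1:50), paste0("s", 1:n)))
  expr <- matrix(rnorm(50 * n), 50, n,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:n)))
  pairs <- data.frame(probe = rownames(meth), gene = rownames(expr))
  r1 <- correlate_meth_expr(meth, expr, pairs)
  perm <- sample(n)
  r2 <- correlate_meth_expr(meth[, perm], expr[, perm], pairs)
  expect_equal(r1, r2, ignore_attr = TRUE)
  # zero-variance probe is skipped with a warning
  meth["cg01", ] <- 0.5
  expect_warning(r3 <- correlate_meth_expr(meth, expr, pairs), "skipped")
  expect_false("cg01" %in% r3$probe)
  # probes with excess missingness are excluded
  meth2 <- meth; meth2["cg02", 1:8] <- NA
  expect_warning(r4 <- correlate_meth_expr(meth2, expr, pairs), "skipped")
  expect_false("cg02" %in% r4$probe)
})

test_that("candidate selection applies the probe-count and beta gates", {
  # 6 probes on GA at beta ~0.8 (hyper), 4 probes on GB at ~0.1
  samples <- paste0("t", 1:6)
  probes <- sprintf("cg%02d", 1:10)
  meth <- rbind(matrix(0.8, 6, 6), matrix(0.1, 4, 6))
  set.seed(16)
  meth <- meth + matrix(rnorm(60, 0, 0.02), 10, 6)
  dimnames(meth) <- list(probes, samples)
  res <- data.frame(probe = probes,
                    gene = rep(c("GA", "GB"), c(6, 4)),
                    n = 6L, slope = -1, t = -8, p = 1e-6, p_adj = 1e-4)
  groups <- setNames(rep("tumor", 6), samples)
  cand <- select_candidate_genes(res, meth, groups, tumor_group = "tumor")
  expect_equal(cand$gene, "GA")          # GB has only 4 qualifying probes
  expect_equal(cand$direction, "hyper")
  expect_gte(cand$n_qualifying, 5L)
  # boundary: mean exactly 0.75 or SD exactly 0.25 does not qualify
  meth2 <- rbind(matrix(0.75, 6, 6))
  dimnames(meth2) <- list(probes[1:6], samples)
  cand2 <- select_candidate_genes(res[1:6, ], meth2, groups)
  expect_equal(nrow(cand2), 0L)
})

test_that("candidate selection equals the brute-force oracle on cohorts", {
  spec <- tiny_spec(seed = 17)
  cohort <- gen_meth_expr(spec)
  pairs <- map_probes_to_genes(cohort$probe_annot, cohort$gene_models)
  res <- correlate_meth_expr(cohort$meth, cohort$expr, pairs)
  tum <- names(cohort$meth_groups)[cohort$meth_groups == "tumor"]
  cand <- select_candidate_genes(res, cohort$meth, cohort$meth_groups,
                                 tumor_group = "tumor", min_probes = 3L)
  oracle <- oracle_select(res, cohort$meth, tum, min_probes = 3L)
  expect_equal(sort(cand$gene), oracle)
})

test_that("bisulfite calls follow the published class boundaries", {
  sites <- data.frame(site = c("a", "b", "c", "d", "e"),
                      c_peak = c(0, 81, 20, 50, 100),
                      t_peak = c(50, 19, 80, 50, 0))
  out <- bisulfite_methylation_call(sites)
  expect_equal(out$ratio, c(0, 0.81, 0.2, 0.5, 1))
  expect_equal(out$class, c("unmethylated", "fully_methylated",
                            "unmethylated", "partially_methylated",
                            "fully_methylated"))
  bad <- data.frame(site = "z", c_peak = 0, t_peak = 0)
  expect_error(bisulfite_methylation_call(bad), "site 'z'")
})
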