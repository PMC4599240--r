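# SAM differential expression, target-gene correlation, GSEA, clustering.

test_that("SAM d matches the closed-form on a hand-computable toy (s0 = 0)", {
  mat <- rbind(g1 = c(1, 2, 3, 7, 8, 9),
               g2 = c(5, 5, 5, 5, 5, 6))
  groups <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  res <- sam_differential(mat, groups, n_perm = 50L, seed = 1L, s0 = 0)
  manual_d <- function(x) {
    a <- x[1:3]; b <- x[4:6]
    s <- sqrt((1 / 3 + 1 / 3) * (sum((a - mean(a))^2) +
                                   sum((b - mean(b))^2)) / 4)
    (mean(a) - mean(b)) / s
  }
  expect_equal(res$d, c(manual_d(mat[1, ]), manual_d(mat[2, ])),
               tolerance = 1e-12)
  expect_equal(res$fold_change, 2^c(mean(mat[1, 1:3]) - mean(mat[1, 4:6]),
                                    mean(mat[2, 1:3]) - mean(mat[2, 4:6])),
               tolerance = 1e-12)
})

test_that("SAM is null under identical group means and errors on bad input", {
  ne <- null_expr(100, 6, 6, seed = 2)
  res <- sam_differential(ne$mat, ne$groups, n_perm = 100L, seed = 3L)
  expect_lt(max(abs(res$d)), 5)
  expect_false(any(res$significant))
  expect_error(sam_differential(ne$mat, factor(rep("A", 12))), "two")
  m2 <- ne$mat; m2[1, 1] <- NA
  expect_error(sam_differential(m2, ne$groups), "missing")
})

test_that("SAM q-values are monotone non-increasing in |d|", {
  set.seed(4)
  ne <- null_expr(80, 5, 5, seed = 4)
  ne$mat[1:10, 1:5] <- ne$mat[1:10, 1:5] + 3   # some real signal
  res <- sam_differential(ne$mat, ne$groups, n_perm = 200L, seed = 5L)
  o <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("pcc_to_target finds perfect and anti correlations", {
  ne <- null_expr(30, 5, 5, seed = 6)
  mat <- ne$mat
  mat["G0002", ] <- mat["G0001", ]                 # duplicate of target
  mat["G0003", ] <- -2 * mat["G0001", ] + 7        # negated + shifted
  res <- pcc_to_target(mat, "G0001")
  expect_true("G0002" %in% res$positive)
  expect_true("G0003" %in% res$negative)
  expect_false("G0001" %in% names(res$r))          # target excluded
  expect_length(intersect(res$positive, res$negative), 0)
  expect_equal(unname(res$r["G0002"]), 1)
  expect_equal(unname(res$r["G0003"]), -1)
})

test_that("pcc_to_target equals a brute-force threshold scan", {
  ne <- null_expr(200, 10, 10, seed = 7)
  res <- pcc_to_target(ne$mat, "G0001", cut = 0.3)
  pos <- neg <- character(0)
  for (g in setdiff(rownames(ne$mat), "G0001")) {
    r <- cor(ne$mat[g, ], ne$mat["G0001", ])
    if (r >= 0.3) pos <- c(pos, g)
    if (r <= -0.3) neg <- c(neg, g)
  }
  expect_setequal(res$positive, pos)
  expect_setequal(res$negative, neg)
  m2 <- ne$mat; m2["G0005", ] <- 3
  expect_warning(pcc_to_target(m2, "G0001", cut = 0.3), "zero-variance")
})

test_that("GSEA degenerate compositions give ES = 1", {
  # singleton set whose gene ranks first
  set.seed(8)
  mat <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:10)))
  groups <- factor(rep(c("A", "B"), each = 5))
  mat["g01", 1:5] <- mat["g01", 1:5] + 10          # dominant ranking
  res <- suppressWarnings(
    gsea_enrichment(mat, groups, list(TOP = "g01"), n_perm = 50L,
                    min_size = 1L, seed = 1L))
  expect_equal(res$es, 1)
  # set = all genes: no miss decrements, ES reaches 1 at the end
  res2 <- suppressWarnings(
    gsea_enrichment(mat, groups, list(ALL = rownames(mat)), n_perm = 50L,
                    min_size = 1L, seed = 1L))
  expect_equal(res2$es, 1)
})

test_that("GSEA running sum equals a hand-stepped oracle on a toy", {
  stat <- c(a = 5, b = 4, c = 3, d = 2, e = 1, f = -1, g = -2, h = -3,
            i = -4, j = -5)
  member <- c("b", "c", "i")
  # independent hand-stepped oracle (weight 1)
  ranked <- names(sort(stat, decreasing = TRUE))
  w <- abs(stat[ranked])
  run <- 0; best <- 0
  nh <- length(member); n <- length(stat)
  denom <- sum(w[ranked %in% member])
  for (gene in ranked) {
    if (gene %in% member) run <- run + w[gene] / denom
    else run <- run - 1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  expect_equal(quiescreen:::gsea_es(stat, member, weight = 1), unname(best),
               tolerance = 1e-12)
})

test_that("GSEA skips undersized sets with a warning", {
  ne <- null_expr(50, 4, 4, seed = 9)
  expect_warning(
    res <- gsea_enrichment(ne$mat, ne$groups,
                           list(SMALL = c("G0001", "G0002"),
                                OK = rownames(ne$mat)[1:12]),
                           n_perm = 50L, min_size = 10L, seed = 1L),
    "skipping")
  expect_equal(res$set, "OK")
})

test_that("average-linkage Pearson clustering behaves and matches an oracle", {
  set.seed(10)
  base <- matrix(rnorm(8 * 6), 8, 6,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  base[, 2] <- base[, 1]                           # identical columns
  hc <- hierarchical_cluster(base)
  # identical columns merge first at height 0
  first <- sort(abs(hc$cols$merge[1, ]))
  expect_equal(first, c(1, 2))
  expect_equal(hc$cols$height[1], 0, tolerance = 1e-12)

  # 4-column toy: manual average-linkage agglomeration on 1 - r
  m <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("g", 1:10),
                                                paste0("s", 1:4)))
  d <- 1 - cor(m)
  hc2 <- hierarchical_cluster(m)$cols
  # oracle: first merge = closest pair; its height = min off-diagonal dist
  off <- d[upper.tri(d)]
  expect_equal(hc2$height[1], min(off), tolerance = 1e-12)
  pair <- which(d == min(off), arr.ind = TRUE)[1, ]
  expect_setequal(abs(hc2$merge[1, ]), as.integer(pair))
  # second merge height from manual average linkage
  rest <- setdiff(1:4, pair)
  d2 <- sapply(rest, function(k) mean(d[k, pair]))
  cand <- c(d[rest[1], rest[2]], d2)
  expect_equal(hc2$height[2], min(cand), tolerance = 1e-12)

  # column order invariance up to mirror: identical merge heights
  perm <- c(3, 1, 4, 2)
  hc3 <- hierarchical_cluster(m[, perm])$cols
  expect_equal(sort(hc3$height), sort(hc2$height), tolerance = 1e-12)

  mz <- m; mz[, 1] <- 2
  expect_error(hierarchical_cluster(mz), "zero-variance column: s1")
  mz <- m; mz["g3", ] <- 1
  expect_error(hierarchical_cluster(mz), "zero-variance row: g3")
})
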