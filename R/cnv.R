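# Copy-number segmentation and quiescence statistics.
#
# Marker-level log2-ratio tracks are partitioned by recursive binary
# segmentation with a permutation change-point test (a desk-scale stand-in
# for circular binary segmentation); segments are then filtered with the
# 8-marker / |log2| > 0.5 rule and summarized per sample.

SEX_CHROMOSOMES <- c("chrX", "chrY", "X", "Y")

# exhaustive single-split mean-shift search (used for degenerate nodes and
# as a reference for the edge-anchored case of the circular statistic).
# Returns c(best index k = size of left part, statistic); the pooled SD is
# constant under within-segment permutation, so it is dropped.
best_split <- function(x, min_width) {
  n <- length(x)
  if (n < 2L * min_width) return(NULL)
  k <- seq.int(min_width, n - min_width)
  s <- cumsum(x)
  tot <- s[n]
  stat <- abs(s[k] / k - (tot - s[k]) / (n - k)) * sqrt(k * (n - k) / n)
  i <- which.max(stat)            # which.max -> leftmost tie
  c(k = k[i], stat = stat[i])
}

# recursive circular binary segmentation of one chromosome; returns segment
# end indices (in marker units).  Each node is tested with the compiled
# two-breakpoint search + permutation test; accepted segments split the
# node into up to three pieces which are recursed.
rbs <- function(x, alpha, min_width, n_perm) {
  n <- length(x)
  if (n < 2L * min_width) return(n)
  res <- cbs_segment_test(x, min_width, n_perm, alpha)
  if (!res$significant) return(n)
  i <- res$i; j <- res$j
  parts <- list(seq_len(i),
                seq.int(i + 1L, j),
                if (j < n) seq.int(j + 1L, n) else integer(0))
  ends <- integer(0); offset <- 0L
  for (p in parts) {
    if (!length(p)) next
    ends <- c(ends, offset + rbs(x[p], alpha, min_width, n_perm))
    offset <- offset + length(p)
  }
  ends
}

#' Segment a marker-level log2-ratio track
#'
#' Recursive circular binary segmentation with a permutation test: at each
#' node the best two-breakpoint segment (the window whose mean departs most
#' from the rest of the node, scaled by its width; leftmost on ties) is
#' found by exhaustive search, its statistic is compared against up to
#' `n_perm` within-node permutations (early-stopped once significance is
#' unattainable), and the segment is accepted when the permutation p-value
#' is at most `alpha`.  Accepted segments split the node into up to three
#' pieces which are recursed, so within every returned segment no admissible
#' window passes the test.  Edge-anchored windows reduce to a single split
#' point, so a plain step is handled as in one-breakpoint binary
#' segmentation.  Segments tile each chromosome and their mean is the
#' arithmetic mean of member log2 ratios.
#'
#' @param track data frame for one sample with columns `chromosome`,
#'   `position` (bp, strictly increasing within chromosome) and `log2`
#'   (finite).
#' @param sample_id sample identifier carried into the output.
#' @param alpha significance level of the permutation test, in (0,1).
#' @param min_width minimum number of markers on each side of a split.
#' @param n_perm number of permutations per tested split.
#' @param seed integer seed; segmentation is deterministic given the seed.
#' @return data frame of segments: `sample_id`, `chromosome`, `start`,
#'   `end` (0-based half-open bp, spanning the member marker positions),
#'   `n_markers`, `mean_log2`, `call` (all `"neutral"`; calls are assigned
#'   by [filter_segments()]).
#' @export
segment_track <- function(track, sample_id = "sample", alpha = 0.01,
                          min_width = 2L, n_perm = 1000L, seed = 1L) {
  stopifnot(is.data.frame(track),
            all(c("chromosome", "position", "log2") %in% names(track)))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (any(!is.finite(track$log2))) stop("log2 ratios must be finite")
  set.seed(seed)
  out <- list()
  for (chr in unique(track$chromosome)) {
    sub <- track[track$chromosome == chr, , drop = FALSE]
    if (is.unsorted(sub$position, strictly = TRUE))
      stop("marker positions must be strictly increasing on ", chr)
    x <- sub$log2
    n <- length(x)
    if (n < min_width) {
      message("chromosome ", chr, " has fewer than ", min_width,
              " markers; returned as a single segment")
      ends <- n
    } else {
      ends <- rbs(x, alpha, min_width, n_perm)
    }
    starts <- c(1L, head(ends, -1L) + 1L)
    out[[chr]] <- data.frame(
      sample_id = sample_id,
      chromosome = chr,
      start = sub$position[starts] - 1L,
      end = sub$position[ends],
      n_markers = as.integer(ends - starts + 1L),
      mean_log2 = vapply(seq_along(ends),
                         function(i) mean(x[starts[i]:ends[i]]), numeric(1)),
      call = "neutral",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "coords") <- "0-based half-open"
  res
}

#' Filter segments to gain/loss calls
#'
#' Applies the published rule: a segment is retained iff it contains at
#' least `min_markers` markers (inclusive) and its mean log2 ratio is
#' strictly greater than `+log2_cut` (gain) or strictly less than
#' `-log2_cut` (loss).  Sex chromosomes are excluded by default since the
#' rule is defined on autosomes.  Order is preserved and the operation is
#' idempotent.
#'
#' @param segments segment data frame (see [segment_track()] / [read_seg()];
#'   `seg_mean` is accepted as an alias for `mean_log2`).
#' @param min_markers minimum marker count, inclusive (default 8).
#' @param log2_cut absolute log2 threshold, strict (default 0.5).
#' @param autosomes_only drop chrX/chrY before filtering (default TRUE).
#' @return the retained segments with `call` set to `"gain"` or `"loss"`.
#' @export
filter_segments <- function(segments, min_markers = 8L, log2_cut = 0.5,
                            autosomes_only = TRUE) {
  mean_col <- if ("mean_log2" %in% names(segments)) "mean_log2" else "seg_mean"
  m <- segments[[mean_col]]
  nm <- if ("n_markers" %in% names(segments)) segments$n_markers else
    segments$num_markers
  keep <- nm >= min_markers & abs(m) > log2_cut
  if (autosomes_only) keep <- keep & !(segments$chromosome %in% SEX_CHROMOSOMES)
  out <- segments[keep, , drop = FALSE]
  out$call <- ifelse(out[[mean_col]] > log2_cut, "gain", "loss")
  rownames(out) <- NULL
  out
}

#' Per-sample quiescence summaries
#'
#' One summary row per requested sample, including samples with no surviving
#' segments (so a fully quiescent genome is reported as a zero, not
#' dropped): the number of filtered segments and the average number of
#' markers per segment (0 when there are none).
#'
#' @param filtered filtered segment data frame (see [filter_segments()]).
#' @param samples character vector of sample ids to report.
#' @return data frame `sample_id`, `n_filtered_segments`,
#'   `mean_markers_per_segment`.
#' @export
quiescence_stats <- function(filtered, samples) {
  nm <- if ("n_markers" %in% names(filtered)) filtered$n_markers else
    filtered$num_markers
  data.frame(
    sample_id = samples,
    n_filtered_segments = vapply(samples, function(s)
      sum(filtered$sample_id == s), integer(1)),
    mean_markers_per_segment = vapply(samples, function(s) {
      v <- nm[filtered$sample_id == s]
      if (length(v)) mean(v) else 0
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
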