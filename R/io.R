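# Readers and writers for the standard formats the pipeline touches.
#
# Coordinate convention: files on disk use 1-based inclusive coordinates
# (the SEG / gene-model convention); everything held in memory by the cnv
# module uses 0-based half-open intervals.  read_seg converts on the way in,
# write_seg inverts the conversion on the way out, so a write-then-read
# round trip is the identity.

SEG_COLUMNS <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")

#' Read a SEG file
#'
#' Reads the tab-delimited Broad SEG dialect (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`; 1-based inclusive coordinates).  Lines
#' starting with `#` are treated as comments.  Coordinates are converted to
#' the package-internal 0-based half-open convention: `start = loc.start - 1`,
#' `end = loc.end` (so `end - start` is the interval width in bp).
#'
#' @param path path to a SEG file with a header row.
#' @return data frame with columns `sample_id`, `chromosome`, `start`,
#'   `end` (0-based half-open), `num_markers`, `seg_mean`.  Attribute
#'   `coords` records the convention.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  missing <- setdiff(SEG_COLUMNS, names(df))
  if (length(missing))
    stop("SEG format error: missing column '", missing[1], "' in ", path)
  if (nrow(df)) {
    bad <- which(df$loc.end < df$loc.start)
    if (length(bad))
      stop("SEG record error at data line ", bad[1],
           ": end < start (", df$loc.end[bad[1]], " < ", df$loc.start[bad[1]], ")")
    if (any(!nzchar(df$chrom)))
      stop("SEG record error: empty chromosome at data line ",
           which(!nzchar(df$chrom))[1])
    if (any(df$num.mark < 1))
      stop("SEG record error: num.mark < 1 at data line ",
           which(df$num.mark < 1)[1])
  }
  out <- data.frame(sample_id = as.character(df$ID),
                    chromosome = as.character(df$chrom),
                    start = df$loc.start - 1L,
                    end = df$loc.end,
                    num_markers = as.integer(df$num.mark),
                    seg_mean = as.numeric(df$seg.mean),
                    stringsAsFactors = FALSE)
  attr(out, "coords") <- "0-based half-open"
  out
}

#' Write segments as a SEG file
#'
#' Inverse of [read_seg()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive `loc.start`/`loc.end`.
#'
#' @param segs data frame as returned by [read_seg()] (columns `sample_id`,
#'   `chromosome`, `start`, `end`, `num_markers`, `seg_mean`;
#'   [segment_track()]'s `n_markers`/`mean_log2` are accepted as aliases).
#' @param path output path.
#' @param cfg optional configuration; when given, a provenance comment line
#'   (seed, config hash, coordinate convention) is written above the header.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segs, path, cfg = NULL) {
  nm <- if ("num_markers" %in% names(segs)) segs$num_markers else
    segs$n_markers
  sm <- if ("seg_mean" %in% names(segs)) segs$seg_mean else segs$mean_log2
  out <- data.frame(ID = segs$sample_id,
                    chrom = segs$chromosome,
                    loc.start = segs$start + 1L,
                    loc.end = segs$end,
                    num.mark = nm,
                    seg.mean = sm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(provenance_header(cfg, "1-based inclusive"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `set name <TAB> description <TAB> symbol...`.  Duplicate
#' symbols within a set are removed with a warning; sets left empty are
#' dropped with a warning; a duplicated set name is an error.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of gene symbols; attribute
#'   `descriptions` holds the per-set description strings.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("GMT format error at line ", i, ": need at least name and description")
    nm <- parts[1]
    if (nm %in% names(sets))
      stop("GMT error: duplicate set name '", nm, "' at line ", i)
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", nm, "': duplicate gene symbols removed")
      genes <- unique(genes)
    }
    if (!length(genes)) {
      warning("GMT set '", nm, "' is empty and was dropped")
      next
    }
    sets[[nm]] <- genes
    descs[nm] <- parts[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (as from [read_gmt()]).
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to the `descriptions` attribute of `sets`, else `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' First column holds the feature id, the header row holds sample ids.
#' `#` comment lines (provenance headers) are skipped.
#'
#' @param path path to a TSV matrix.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample TSV matrix
#'
#' @param mat numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_name header name for the feature-id column.
#' @param cfg optional configuration for a provenance comment line.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "feature", cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(provenance_header(cfg), con)
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic TSV table (provenance comments skipped)
#'
#' @param path path to a tab-delimited file with a header row.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Write a generic TSV table with an optional provenance header
#'
#' @param df data frame.
#' @param path output path.
#' @param cfg optional configuration for a provenance comment line.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(provenance_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON result report with provenance metadata
#'
#' @param results list of results (must be JSON-representable).
#' @param path output path.
#' @param cfg configuration; seed and config hash are embedded under `meta`.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(results, path, cfg) {
  obj <- list(meta = list(seed = cfg$seed, config_md5 = config_hash(cfg),
                          coords = "files 1-based inclusive; internal 0-based half-open"),
              results = results)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
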