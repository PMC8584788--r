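# Segment-table IO and validation.
#
# A segment table is a tibble with one row per genomic interval and columns
#   sample_id, chrom, start, end, copy_number, cn_state, allelic_state
# Coordinates are 1-based inclusive; width = end - start + 1.

CN_STATES <- c("gain", "loss", "neutral")
ALLELIC_STATES <- c("balanced", "AI", "LOH", "unknown")

seg_width <- function(segments) segments$end - segments$start + 1

#' Construct and validate a segment table
#'
#' @param x data frame with columns `sample_id`, `chrom`, `start`, `end` and
#'   optionally `copy_number`, `cn_state`, `allelic_state`. Missing state
#'   columns are filled with `"neutral"` / `"unknown"`; missing `copy_number`
#'   with `NA`.
#' @param ref optional [genome_reference()]; when given, chromosome names are
#'   checked against it and segment ends against chromosome lengths.
#' @return a validated segment tibble.
#' @export
segment_table <- function(x, ref = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("sample_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("segment table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"copy_number" %in% names(x)) x$copy_number <- NA_integer_
  if (!"cn_state" %in% names(x)) x$cn_state <- "neutral"
  if (!"allelic_state" %in% names(x)) x$allelic_state <- "unknown"
  x <- dplyr::select(x, dplyr::all_of(c("sample_id", "chrom", "start", "end",
                                        "copy_number", "cn_state", "allelic_state")))
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)

  bad <- which(x$end < x$start)
  if (length(bad) > 0) {
    abort(sprintf("malformed segment at row %d: end (%s) < start (%s)",
                  bad[1], format(x$end[bad[1]], scientific = FALSE),
                  format(x$start[bad[1]], scientific = FALSE)))
  }
  if (any(x$start < 1)) abort("segment start must be >= 1")
  bad_cn <- !x$cn_state %in% CN_STATES
  if (any(bad_cn)) {
    abort(paste0("unknown cn_state: ", paste(unique(x$cn_state[bad_cn]), collapse = ", ")))
  }
  bad_al <- !x$allelic_state %in% ALLELIC_STATES
  if (any(bad_al)) {
    abort(paste0("unknown allelic_state: ",
                 paste(unique(x$allelic_state[bad_al]), collapse = ", ")))
  }
  if (!is.null(ref)) {
    unknown <- setdiff(unique(x$chrom), ref$chrom)
    if (length(unknown) > 0) {
      abort(paste0("chromosome(s) not in genome reference: ",
                   paste(unknown, collapse = ", ")))
    }
    too_long <- x$end > ref_lookup(ref, x$chrom, "length")
    if (any(too_long)) {
      abort(sprintf("segment at row %d extends beyond chromosome %s",
                    which(too_long)[1], x$chrom[which(too_long)[1]]))
    }
  }
  x
}

#' Read a segment table from a TSV file
#'
#' Two dialects are supported:
#' * `"generic"`: columns `sample  chrom  start  end  cn  cn_state  allelic_state`.
#' * `"freec_cnv"`: Control-FREEC CNV output, columns
#'   `chrom  start  end  copy_number  status` with `status` in
#'   {gain, loss, normal}; `sample_id` is taken from the `sample_id` argument
#'   (default: file name without extension).
#'
#' @param path file path.
#' @param dialect `"generic"` or `"freec_cnv"`.
#' @param ref optional [genome_reference()] for coordinate validation.
#' @param sample_id sample name used for the FREEC dialect (one sample per
#'   file).
#' @return a segment tibble (see [segment_table()]).
#' @export
read_segments <- function(path, dialect = c("generic", "freec_cnv"),
                          ref = NULL, sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0) {
    warn(paste0("no data rows in ", path))
    return(segment_table(tibble(sample_id = character(), chrom = character(),
                                start = numeric(), end = numeric())))
  }
  if (dialect == "generic") {
    required <- c("sample", "chrom", "start", "end")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0) {
      abort(paste0("generic dialect requires column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    out <- tibble(
      sample_id = as.character(tab$sample),
      chrom = as.character(tab$chrom),
      start = tab$start, end = tab$end,
      copy_number = if ("cn" %in% names(tab)) as.integer(tab$cn) else NA_integer_,
      cn_state = if ("cn_state" %in% names(tab)) tab$cn_state else "neutral",
      allelic_state = if ("allelic_state" %in% names(tab)) tab$allelic_state else "unknown"
    )
  } else {
    required <- c("chrom", "start", "end", "copy_number", "status")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0) {
      abort(paste0("freec_cnv dialect requires column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    bad <- !tab$status %in% c("gain", "loss", "normal")
    if (any(bad)) {
      abort(paste0("unknown FREEC status: ",
                   paste(unique(tab$status[bad]), collapse = ", ")))
    }
    out <- tibble(
      sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
      chrom = as.character(tab$chrom),
      start = tab$start, end = tab$end,
      copy_number = as.integer(tab$copy_number),
      cn_state = ifelse(tab$status == "normal", "neutral", tab$status),
      allelic_state = "unknown"
    )
  }
  segment_table(out, ref = ref)
}

#' Write a segment table as generic-dialect TSV
#'
#' @param segments segment tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- tibble(sample = segments$sample_id, chrom = segments$chrom,
                start = segments$start, end = segments$end,
                cn = segments$copy_number, cn_state = segments$cn_state,
                allelic_state = segments$allelic_state)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Error if any two segments of one sample overlap on a chromosome.
check_no_overlap <- function(segments) {
  by_group <- split(segments, paste(segments$sample_id, segments$chrom, sep = "\r"))
  for (g in by_group) {
    if (nrow(g) < 2) next
    o <- order(g$start, g$end)
    if (any(g$start[o][-1] <= g$end[o][-nrow(g)])) {
      abort(sprintf("overlapping segments on %s for sample %s",
                    g$chrom[1], g$sample_id[1]))
    }
  }
  invisible(TRUE)
}
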