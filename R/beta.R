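# Beta-value matrices and labeled cohorts.
#
# A beta matrix is a plain numeric matrix, probes in rows (rownames = probe
# ids) and samples in columns (colnames = sample ids), values in [0, 1].

#' Validate a beta matrix
#'
#' @param m numeric matrix, probes x samples, with row and column names.
#' @param allow_missing tolerate `NA` cells?
#' @return the validated matrix, invisibly usable downstream.
#' @export
beta_matrix <- function(m, allow_missing = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) abort("beta matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("beta matrix needs probe rownames and sample colnames")
  }
  if (nrow(m) < 1 || ncol(m) < 1) abort("beta matrix needs >= 1 probe and >= 1 sample")
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicate probe id: ",
                 rownames(m)[duplicated(rownames(m))][1]))
  }
  if (anyDuplicated(colnames(m))) {
    abort(paste0("duplicate sample id: ",
                 colnames(m)[duplicated(colnames(m))][1]))
  }
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("beta value out of [0,1] at probe %s, sample %s (%g)",
                  rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                  m[bad[1, 1], bad[1, 2]]))
  }
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    if (!allow_missing) abort(sprintf("%d missing beta values", n_missing))
    inform(sprintf("beta matrix contains %d missing values", n_missing))
  }
  m
}

#' Read a beta-value matrix from CSV/TSV
#'
#' First column: probe ids; header row: sample ids. The delimiter is taken
#' from the file extension (`.csv` -> comma, otherwise tab).
#'
#' @param path file path.
#' @return numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  tab <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort("beta matrix file needs a probe column and >= 1 sample column")
  probes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  beta_matrix(m)
}

#' Write a beta matrix to CSV/TSV
#'
#' @param m beta matrix.
#' @param path output path; a `.csv` extension selects comma delimiting.
#' @param digits decimal digits written (default full precision).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, digits = NULL) {
  vals <- if (is.null(digits)) m else round(m, digits)
  tab <- tibble::as_tibble(vals)
  tab <- dplyr::bind_cols(tibble(probe_id = rownames(m)), tab)
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::write_csv else readr::write_tsv
  writer(tab, path, progress = FALSE)
  invisible(path)
}

#' Harmonize beta matrices across array platforms
#'
#' Restricts every matrix to the common probe set (probe order: the first
#' matrix's order, filtered) and concatenates samples, mirroring the
#' EPIC-to-450k conversion that drops probes differing between platforms.
#' No signal rescaling is performed.
#'
#' @param matrices list of >= 2 beta matrices with disjoint sample ids.
#' @return one beta matrix over the probe intersection.
#' @export
harmonize_beta <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) {
    abort("harmonize_beta needs a list of >= 2 matrices")
  }
  all_samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_samples)) {
    abort(paste0("shared sample id across matrices: ",
                 all_samples[duplicated(all_samples)][1]))
  }
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (length(common) == 0) abort("no probes shared by all matrices")
  common <- rownames(matrices[[1]])[rownames(matrices[[1]]) %in% common]
  out <- do.call(cbind, lapply(matrices, function(m) m[common, , drop = FALSE]))
  beta_matrix(out)
}

#' Attach BRCAness labels to a beta matrix
#'
#' Builds a labeled cohort: the matrix plus per-sample scores and the labels
#' obtained by thresholding them under `scheme`.
#'
#' @param matrix beta matrix (probes x samples).
#' @param scores per-sample scores: a named numeric vector or a data frame
#'   with columns `sample_id` and `score`.
#' @param scheme a [threshold_scheme()].
#' @param require_both_classes error (rather than warn) when all samples land
#'   in one class; training operations need both.
#' @return a `labeled_cohort` object.
#' @export
attach_labels <- function(matrix, scores, scheme = threshold_scheme("PGC_NEXUS"),
                          require_both_classes = FALSE) {
  matrix <- beta_matrix(matrix)
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$sample_id)
  }
  missing_samples <- setdiff(colnames(matrix), names(scores))
  if (length(missing_samples) > 0) {
    abort(paste0("no score for sample(s): ", paste(missing_samples, collapse = ", ")))
  }
  scores <- scores[colnames(matrix)]
  labels <- label_brcaness(scores, scheme)
  names(labels) <- colnames(matrix)
  sizes <- table(labels)
  inform(sprintf("labeled cohort: %d positive / %d negative",
                 sizes[["positive"]], sizes[["negative"]]))
  if (any(sizes == 0)) {
    msg <- "all samples fall in a single class"
    if (require_both_classes) abort(msg) else warn(msg)
  }
  structure(list(beta = matrix, scores = scores, labels = labels, scheme = scheme),
            class = "labeled_cohort")
}

#' Construct a labeled cohort directly from labels
#'
#' Lower-level companion to [attach_labels()] for callers that already hold
#' labels (e.g. the synthetic-data generator).
#'
#' @param matrix beta matrix.
#' @param labels per-sample labels (named, or in matrix column order).
#' @param scores optional per-sample scores (defaults to 1/0 by label).
#' @param scheme a [threshold_scheme()] carried as provenance.
#' @return a `labeled_cohort` object.
#' @export
labeled_cohort <- function(matrix, labels, scores = NULL,
                           scheme = threshold_scheme("PGC_NEXUS")) {
  matrix <- beta_matrix(matrix)
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  if (length(labels) != ncol(matrix)) abort("one label per sample required")
  if (anyNA(labels)) abort("labels must be 'positive' or 'negative'")
  names(labels) <- colnames(matrix)
  if (is.null(scores)) scores <- as.numeric(labels == "positive")
  if (is.null(names(scores))) names(scores) <- colnames(matrix)
  structure(list(beta = matrix, scores = scores[colnames(matrix)],
                 labels = labels, scheme = scheme),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("<labeled_cohort: %d probes x %d samples; %d positive / %d negative; scheme %s>\n",
              nrow(x$beta), ncol(x$beta), sizes[["positive"]], sizes[["negative"]],
              x$scheme$name))
  invisible(x)
}

#' Per-sample summary of a labeled cohort
#'
#' @param x a `labeled_cohort`.
#' @param ... unused.
#' @return tibble with `sample_id`, `score`, `label`.
#' @method tidy labeled_cohort
#' @export
tidy.labeled_cohort <- function(x, ...) {
  tibble(sample_id = colnames(x$beta), score = unname(x$scores),
         label = unname(x$labels))
}

# Subset a cohort to given sample ids (order preserved as given).
cohort_subset <- function(cohort, sample_ids) {
  labeled_cohort(cohort$beta[, sample_ids, drop = FALSE],
                 cohort$labels[sample_ids],
                 cohort$scores[sample_ids],
                 cohort$scheme)
}

#' Select score-extreme samples from each class
#'
#' Keeps the `floor(fraction * class size)` highest-scoring positives and
#' lowest-scoring negatives, optionally after intersecting each class with an
#' availability subset (e.g. samples that also have RNA-seq). This mirrors the
#' "two-thirds of the top / bottom of the score-ranked list" selection used to
#' avoid samples near the labeling threshold. Score ties are broken by sample
#' id.
#'
#' @param cohort a `labeled_cohort`.
#' @param fraction fraction of each class to keep, in (0, 1].
#' @param available optional character vector restricting the candidates.
#' @return tibble with `sample_id`, `label`, `score`, positives first.
#' @export
select_extremes <- function(cohort, fraction = 2 / 3, available = NULL) {
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  info <- tidy(cohort)
  if (!is.null(available)) info <- info[info$sample_id %in% available, , drop = FALSE]
  take <- function(class, decreasing) {
    cls <- info[info$label == class, , drop = FALSE]
    if (nrow(cls) == 0) abort(paste0("no available samples in class ", class))
    k <- floor(fraction * nrow(cls))
    o <- order(if (decreasing) -cls$score else cls$score, cls$sample_id)
    cls[o, , drop = FALSE][seq_len(k), , drop = FALSE]
  }
  dplyr::bind_rows(take("positive", TRUE), take("negative", FALSE))
}
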