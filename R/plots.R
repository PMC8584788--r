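# ggplot2 views of the result objects.

#' ROC curves of a cross-validation run
#'
#' Draws the per-fold ROC curves (thin) and the combined pooled-vote curve
#' (thick), with the chance diagonal.
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  fold_curves <- dplyr::bind_rows(lapply(seq_len(object$k), function(i) {
    v <- object$votes[object$votes$fold == i, , drop = FALSE]
    dplyr::bind_cols(tibble(fold = factor(i)), roc_auc(v$vote_fraction, v$truth)$curve)
  }))
  ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(data = fold_curves,
                       ggplot2::aes(x = .data$fpr, y = .data$tpr, group = .data$fold),
                       colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_step(data = object$combined_roc,
                       ggplot2::aes(x = .data$fpr, y = .data$tpr),
                       colour = "black", linewidth = 1) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Combined AUC = %.2f", object$combined_auc)) +
    ggplot2::theme_minimal()
}

#' Null distribution of the label-permutation test
#'
#' Histogram of permuted positive-delta counts with the observed count
#' marked.
#'
#' @param object a `permutation_null`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot permutation_null
#' @export
autoplot.permutation_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$positive_count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_positive_count,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "Probes with positive delta-variance (permuted labels)",
                  y = "Permutations",
                  title = sprintf("Observed %d, empirical p = %.3g",
                                  object$observed_positive_count, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Delta-variance rank plot
#'
#' Delta against rank, with the positive-delta region above zero; useful to
#' eyeball how many probes carry class structure.
#'
#' @param table a [delta_variances()] tibble.
#' @param top_k optionally highlight the first `top_k` ranks.
#' @return a ggplot object.
#' @export
plot_delta_variances <- function(table, top_k = NULL) {
  table <- dplyr::mutate(table,
                         selected = if (is.null(top_k)) FALSE else .data$rank <= top_k)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$rank, y = .data$delta,
                                      colour = .data$selected)) +
    ggplot2::geom_point(size = 0.5, show.legend = !is.null(top_k)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Rank", y = "Delta-variance") +
    ggplot2::theme_minimal()
}

#' Enrichment-score bar chart
#'
#' Signed ES per gene set, filled by FWER significance at `alpha`.
#'
#' @param results an [enrich()] tibble.
#' @param alpha FWER significance level for the fill.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(results, alpha = 0.05) {
  results <- dplyr::mutate(results, significant = .data$fwer_p < alpha)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$es, y = stats::reorder(.data$name, .data$es),
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = sprintf("FWER < %.2g", alpha)) +
    ggplot2::labs(x = "Enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked scar-score bar chart
#'
#' LOH, TAI and LST counts stacked per sample, ordered by HRD sum, with the
#' scheme cutoff drawn when the HRD scheme is used.
#'
#' @param scores a [scar_scores()] tibble.
#' @param cutoff optional horizontal reference line (e.g. 42 for HRD).
#' @return a ggplot object.
#' @export
plot_scar_scores <- function(scores, cutoff = NULL) {
  long <- tidyr::pivot_longer(
    scores[, c("sample_id", "loh_count", "tai_count", "lst_count", "hrd_sum")],
    c("loh_count", "tai_count", "lst_count"),
    names_to = "component", values_to = "count")
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = stats::reorder(.data$sample_id, .data$hrd_sum),
                                    y = .data$count, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Scar count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}
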