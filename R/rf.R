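# Class-balanced random-forest BRCAness classifier, nested cross-validation,
# confusion-matrix metrics and ROC/AUC.

#' Random-forest hyperparameters
#'
#' Defaults follow the published classifier: 10,000 trees, 32 variables
#' tried at each node (capped at the feature count at train time), minimum
#' node size 3, no depth limit, and per-tree stratified balancing that draws
#' min-class-size bootstrap samples from each class.
#'
#' @param n_trees number of trees.
#' @param vars_per_node variables tried at each split (`mtry`).
#' @param min_node_size minimum terminal node size.
#' @param balanced_sampling draw equal per-class bootstrap samples per tree?
#' @param seed integer seed used at training.
#' @return an `rf_params` list.
#' @export
rf_params <- function(n_trees = 10000, vars_per_node = 32, min_node_size = 3,
                      balanced_sampling = TRUE, seed = 1) {
  if (n_trees < 1) abort("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_node = as.integer(vars_per_node),
                 min_node_size = as.integer(min_node_size),
                 balanced_sampling = isTRUE(balanced_sampling),
                 seed = as.integer(seed)),
            class = "rf_params")
}

# Fit the underlying forest on a samples-x-features matrix.
fit_forest <- function(x, y, params, seed = params$seed) {
  set.seed(seed)
  mtry <- min(params$vars_per_node, ncol(x))
  if (params$balanced_sampling) {
    m <- min(table(y))
    randomForest::randomForest(
      x = x, y = y, ntree = params$n_trees, mtry = mtry,
      nodesize = params$min_node_size, replace = TRUE,
      strata = y, sampsize = c(negative = m, positive = m))
  } else {
    randomForest::randomForest(
      x = x, y = y, ntree = params$n_trees, mtry = mtry,
      nodesize = params$min_node_size, replace = TRUE)
  }
}

# Strict vote rule: a sample is BRCAness-positive iff its vote fraction
# exceeds 0.5 (exactly 0.5 stays negative).
vote_label <- function(vote_fraction) {
  factor(ifelse(vote_fraction > 0.5, "positive", "negative"),
         levels = c("negative", "positive"))
}

# 2x2 confusion cells from truth and predicted labels (positive class =
# BRCAness-positive), as a one-row tibble.
confusion_cells <- function(truth, predicted) {
  truth <- truth == "positive"
  predicted <- predicted == "positive"
  tibble(tp = sum(truth & predicted), fp = sum(!truth & predicted),
         tn = sum(!truth & !predicted), fn = sum(truth & !predicted))
}

#' Train the BRCAness classifier
#'
#' Trains a random forest on the given probes with per-tree class balancing
#' and records the out-of-bag (OOB) vote fractions and confusion matrix
#' (OOB votes above 0.5 predict BRCAness-positive).
#'
#' @param cohort a `labeled_cohort` with both classes present.
#' @param probes probe ids to train on (subset of the matrix).
#' @param params [rf_params()].
#' @return a `brcaness_model`.
#' @export
train_brcaness <- function(cohort, probes, params = rf_params()) {
  if (length(probes) == 0) abort("empty probe list")
  missing_probes <- setdiff(probes, rownames(cohort$beta))
  if (length(missing_probes) > 0) {
    abort(paste0("probe(s) not in matrix: ", paste(head(missing_probes, 3), collapse = ", ")))
  }
  sizes <- table(cohort$labels)
  if (any(sizes == 0)) abort("training requires both classes")
  x <- t(cohort$beta[probes, , drop = FALSE])
  fit <- fit_forest(x, cohort$labels, params)
  oob_votes <- fit$votes[, "positive"]
  oob_pred <- vote_label(oob_votes)
  structure(list(forest = fit, selected_probes = probes, params = params,
                 training_class_sizes = c(negative = unname(sizes[["negative"]]),
                                          positive = unname(sizes[["positive"]])),
                 oob_votes = oob_votes,
                 oob_confusion = confusion_cells(cohort$labels, oob_pred),
                 version = as.character(utils::packageVersion("brcaness"))),
            class = "brcaness_model")
}

#' @export
print.brcaness_model <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<brcaness_model: %d probes, %d trees, OOB accuracy %.1f%%>\n",
              length(x$selected_probes), x$params$n_trees, g$oob_accuracy))
  invisible(x)
}

#' Predict BRCAness vote fractions for new samples
#'
#' The vote fraction is the share of trees voting BRCAness-positive; a
#' fraction strictly above 0.5 classifies the sample as positive.
#'
#' @param object a `brcaness_model`.
#' @param matrix beta matrix containing all model probes.
#' @param ... unused.
#' @return tibble with `sample_id`, `vote_fraction`, `label`.
#' @export
predict.brcaness_model <- function(object, matrix, ...) {
  missing_probes <- setdiff(object$selected_probes, rownames(matrix))
  if (length(missing_probes) > 0) {
    abort(paste0("matrix lacks model probe(s): ",
                 paste(head(missing_probes, 5), collapse = ", ")))
  }
  x <- t(matrix[object$selected_probes, , drop = FALSE])
  votes <- predict(object$forest, x, type = "vote")[, "positive"]
  tibble(sample_id = colnames(matrix), vote_fraction = unname(votes),
         label = vote_label(votes))
}

#' Probe importances of a trained model
#'
#' @param x a `brcaness_model`.
#' @param ... unused.
#' @return tibble with `probe_id`, `importance` (mean decrease in Gini
#'   impurity), in decreasing order.
#' @method tidy brcaness_model
#' @export
tidy.brcaness_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest, type = 2)[, 1]
  out <- tibble(probe_id = names(imp), importance = unname(imp))
  out[order(-out$importance, out$probe_id), , drop = FALSE]
}

#' One-row summary of a trained model
#'
#' @param x a `brcaness_model`.
#' @param ... unused.
#' @return one-row tibble with OOB metrics and key parameters.
#' @method glance brcaness_model
#' @export
glance.brcaness_model <- function(x, ...) {
  m <- confusion_metrics(x$oob_confusion)
  tibble(n_probes = length(x$selected_probes), n_trees = x$params$n_trees,
         oob_accuracy = m$accuracy, oob_sensitivity = m$sensitivity,
         oob_specificity = m$specificity, seed = x$params$seed)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN) x 100`,
#' `sensitivity = TP / (TP + FN) x 100`,
#' `specificity = TN / (TN + FP) x 100`. With `rounded = TRUE`, values are
#' rounded to the nearest integer percent (the reporting convention); full
#' precision is the default. A zero denominator yields `NA` (undefined).
#'
#' @param cm one-row tibble or named list with `tp`, `fp`, `tn`, `fn`.
#' @param rounded round to integer percents?
#' @return one-row tibble with `accuracy`, `sensitivity`, `specificity` (%).
#' @examples
#' confusion_metrics(list(tp = 22, tn = 13, fp = 3, fn = 3), rounded = TRUE)
#' @export
confusion_metrics <- function(cm, rounded = FALSE) {
  safe_pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) abort("empty confusion matrix")
  out <- tibble(accuracy = safe_pct(cm$tp + cm$tn, total),
                sensitivity = safe_pct(cm$tp, cm$tp + cm$fn),
                specificity = safe_pct(cm$tn, cm$tn + cm$fp))
  if (rounded) out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), round))
  out
}

#' ROC curve and AUC from vote fractions
#'
#' Sweeps the vote threshold over the observed values and integrates the
#' curve by the trapezoid rule (equivalent to the Mann-Whitney pair-counting
#' statistic with ties counted one half).
#'
#' @param votes numeric scores (vote fractions).
#' @param labels classes, coercible to factor(negative, positive).
#' @return list with `curve` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(votes, labels) {
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  if (length(unique(labels)) < 2) abort("ROC needs both classes")
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  o <- order(-votes)
  v <- votes[o]
  pos <- labels[o] == "positive"
  last_of_tie <- c(v[-1] != v[-length(v)], TRUE)
  tp <- cumsum(pos)[last_of_tie]
  fp <- cumsum(!pos)[last_of_tie]
  curve <- tibble(threshold = c(Inf, v[last_of_tie]),
                  fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  list(curve = curve, auc = auc)
}

# Stratified fold assignment: shuffle within class, split into k folds with
# remainders going to the earliest folds. Returns an integer fold id per sample.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- sample(which(labels == cls))
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    folds[idx] <- rep(seq_len(k), times = sizes)
  }
  folds
}

#' Nested cross-validation of the BRCAness classifier
#'
#' Stratified k-fold cross-validation with the full feature-selection chain
#' (delta-variance ranking, top-k cut, greedy decorrelation) re-run inside
#' each fold on the training samples only, so no information from held-out
#' samples leaks into feature selection. Fold confusion matrices are pooled
#' elementwise and the combined AUC is computed from the pooled held-out
#' votes (not as a mean of per-fold AUCs). Fold models are discarded.
#'
#' @param cohort a `labeled_cohort` with >= k samples per class.
#' @param k number of folds (default 5).
#' @param top_k,rho_max,cor_method feature-selection parameters passed to
#'   [rank_top_k()] and [decorrelate()].
#' @param params [rf_params()] for the fold models.
#' @param seed integer seed controlling fold assignment and fold training.
#' @return a `cv_result` (see [tidy.cv_result()] and [glance.cv_result()]).
#' @export
nested_cv <- function(cohort, k = 5, top_k = 2000, rho_max = 0.8,
                      cor_method = c("spearman", "pearson"),
                      params = rf_params(), seed = 1) {
  cor_method <- match.arg(cor_method)
  sizes <- table(cohort$labels)
  if (any(sizes < k)) abort(sprintf("each class needs >= %d samples for %d folds", k, k))
  seeds <- derive_seeds(seed, k + 1)
  folds <- stratified_folds(cohort$labels, k, seeds[k + 1])
  samples <- colnames(cohort$beta)

  fold_rows <- list()
  vote_rows <- list()
  fold_probes <- list()
  fold_aucs <- numeric(k)
  for (i in seq_len(k)) {
    train_ids <- samples[folds != i]
    test_ids <- samples[folds == i]
    train_cohort <- cohort_subset(cohort, train_ids)
    dv <- delta_variances(train_cohort)
    ranked <- rank_top_k(dv, min(top_k, nrow(dv)))
    retained <- decorrelate(train_cohort$beta, ranked, rho_max = rho_max,
                            method = cor_method)
    model <- train_brcaness(train_cohort, retained,
                            params = rf_params(params$n_trees, params$vars_per_node,
                                               params$min_node_size,
                                               params$balanced_sampling,
                                               seed = seeds[i]))
    pred <- predict(model, cohort$beta[, test_ids, drop = FALSE])
    truth <- cohort$labels[test_ids]
    fold_rows[[i]] <- dplyr::bind_cols(tibble(fold = i),
                                       confusion_cells(truth, pred$label))
    fold_aucs[i] <- roc_auc(pred$vote_fraction, truth)$auc
    vote_rows[[i]] <- tibble(sample_id = test_ids, fold = i,
                             vote_fraction = pred$vote_fraction,
                             predicted = pred$label, truth = unname(truth))
    fold_probes[[i]] <- retained
  }
  fold_confusions <- dplyr::bind_rows(fold_rows)
  votes <- dplyr::bind_rows(vote_rows)
  pooled <- dplyr::summarise(fold_confusions, tp = sum(.data$tp), fp = sum(.data$fp),
                             tn = sum(.data$tn), fn = sum(.data$fn))
  combined <- roc_auc(votes$vote_fraction, votes$truth)
  structure(list(fold_confusions = fold_confusions, pooled_confusion = pooled,
                 fold_aucs = fold_aucs, combined_auc = combined$auc,
                 combined_roc = combined$curve, fold_probes = fold_probes,
                 votes = votes, k = k, seed = seed,
                 fs = list(top_k = top_k, rho_max = rho_max, cor_method = cor_method),
                 folds = setNames(folds, samples)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cv_result: %d folds, combined AUC %.3f, pooled accuracy %.0f%%>\n",
              x$k, g$combined_auc, g$pooled_accuracy))
  invisible(x)
}

#' Held-out votes of a cross-validation run
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return tibble with one row per sample: `sample_id`, `fold`,
#'   `vote_fraction`, `predicted`, `truth`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$votes

#' One-row summary of a cross-validation run
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return one-row tibble with combined AUC, mean fold AUC and pooled
#'   confusion metrics.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  m <- confusion_metrics(x$pooled_confusion)
  tibble(k = x$k, combined_auc = x$combined_auc,
         mean_fold_auc = mean(x$fold_aucs),
         pooled_accuracy = m$accuracy, pooled_sensitivity = m$sensitivity,
         pooled_specificity = m$specificity, seed = x$seed)
}
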