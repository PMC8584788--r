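# Delta-variance feature selection, permutation null, sample-exclusion scan,
# and shadow-feature significance.
#
# The per-probe statistic is
#   delta = var_all - (var_pos + var_neg)
# where var_all is the sample variance over all samples and var_pos/var_neg
# the within-class sample variances (denominator n - 1). Probes whose
# between-class separation exceeds the summed within-class spread get
# delta > 0 and are considered informative.

pos_idx <- function(cohort) which(cohort$labels == "positive")

# delta vector for an arbitrary positive-sample index set (used by the
# permutation null and the exclusion scan without rebuilding tibbles).
delta_for_labels <- function(beta, pos, var_all = NULL) {
  if (is.null(var_all)) var_all <- row_vars(beta)
  var_all - row_vars(beta[, pos, drop = FALSE]) -
    row_vars(beta[, -pos, drop = FALSE])
}

#' Per-probe delta-variance table
#'
#' Computes `var_all`, `var_pos`, `var_neg` (sample variances, denominator
#' n - 1), `delta = var_all - (var_pos + var_neg)` and descending ranks
#' (ties broken by probe id). Probes with any missing value are dropped
#' first, with a message.
#'
#' @param cohort a `labeled_cohort` with >= 2 samples per class.
#' @return tibble with columns `probe_id`, `var_all`, `var_pos`, `var_neg`,
#'   `delta`, `rank`.
#' @export
delta_variances <- function(cohort) {
  beta <- cohort$beta
  incomplete <- rowSums(is.na(beta)) > 0
  if (any(incomplete)) {
    inform(sprintf("dropping %d probe(s) with missing values", sum(incomplete)))
    beta <- beta[!incomplete, , drop = FALSE]
  }
  sizes <- table(cohort$labels)
  if (any(sizes < 2)) abort("each class needs >= 2 samples for variance")
  pos <- pos_idx(cohort)
  var_all <- row_vars(beta)
  var_pos <- row_vars(beta[, pos, drop = FALSE])
  var_neg <- row_vars(beta[, -pos, drop = FALSE])
  out <- tibble(probe_id = rownames(beta), var_all = unname(var_all),
                var_pos = unname(var_pos), var_neg = unname(var_neg),
                delta = unname(var_all - (var_pos + var_neg)))
  out$rank <- rank(order(order(-out$delta, out$probe_id)))
  out[order(out$rank), , drop = FALSE]
}

#' Top-k probes by delta-variance rank
#'
#' @param table a [delta_variances()] tibble.
#' @param k number of probes to keep (default 2000).
#' @return character vector of probe ids in rank order.
#' @export
rank_top_k <- function(table, k = 2000) {
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(table)) {
    warn(sprintf("k = %d exceeds the %d available probes; returning all", k, nrow(table)))
    k <- nrow(table)
  }
  table$probe_id[order(table$rank)][seq_len(k)]
}

#' Greedy decorrelation of a ranked probe list
#'
#' Walks the probes in rank order and keeps a probe only if its absolute
#' correlation with every already-kept probe is at most `rho_max`; the
#' top-ranked probe is always kept. This removes the importance bias that
#' blocks of highly correlated probes would otherwise induce in the forest.
#' Probes with zero variance (correlation undefined) are dropped with a
#' warning.
#'
#' @param matrix beta matrix (probes x samples) holding the samples on which
#'   correlations are computed (training samples only, in cross-validation).
#' @param ranked_probes probe ids in rank order, subset of the matrix rows.
#' @param rho_max correlation ceiling (default 0.8).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return character vector of retained probe ids, in rank order.
#' @export
decorrelate <- function(matrix, ranked_probes, rho_max = 0.8,
                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  missing_probes <- setdiff(ranked_probes, rownames(matrix))
  if (length(missing_probes) > 0) {
    abort(paste0("probe(s) not in matrix: ", paste(head(missing_probes, 3), collapse = ", ")))
  }
  x <- matrix[ranked_probes, , drop = FALSE]
  if (method == "spearman") x <- row_ranks(x)
  n <- ncol(x)
  sds <- sqrt(row_vars(x))
  degenerate <- sds == 0
  if (any(degenerate)) {
    warn(sprintf("dropping %d zero-variance probe(s) from correlation screening",
                 sum(degenerate)))
    x <- x[!degenerate, , drop = FALSE]
    ranked_probes <- ranked_probes[!degenerate]
    sds <- sds[!degenerate]
  }
  m <- nrow(x)
  if (m == 0) return(character(0))
  z <- t((x - rowMeans(x)) / sds)          # samples x probes, standardized
  kept <- matrix(0, nrow = n, ncol = m)
  kept_ids <- character(m)
  count <- 0L
  for (j in seq_len(m)) {
    if (count > 0) {
      rho <- crossprod(kept[, seq_len(count), drop = FALSE], z[, j]) / (n - 1)
      if (any(abs(rho) > rho_max)) next
    }
    count <- count + 1L
    kept[, count] <- z[, j]
    kept_ids[count] <- ranked_probes[j]
  }
  kept_ids[seq_len(count)]
}

#' Label-permutation test of class structure
#'
#' Counts the probes with positive delta-variance under the observed labels,
#' then under `n_perm` label permutations that preserve class sizes. The
#' empirical p-value is `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param cohort a `labeled_cohort`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; the null is bit-reproducible given it.
#' @return a `permutation_null` object (see [tidy.permutation_null()]).
#' @export
permute_class_structure <- function(cohort, n_perm = 1000, seed = 1) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  beta <- cohort$beta
  beta <- beta[rowSums(is.na(beta)) == 0, , drop = FALSE]
  pos <- pos_idx(cohort)
  n <- ncol(beta)
  var_all <- row_vars(beta)
  observed <- sum(delta_for_labels(beta, pos, var_all) > 0)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n, length(pos))
    sum(delta_for_labels(beta, p, var_all) > 0)
  }, integer(1))
  inform(sprintf("permutation null: observed %d positive deltas, seed %d", observed, seed))
  structure(list(observed_positive_count = observed,
                 null_counts = null_counts, n_perm = n_perm, seed = seed,
                 empirical_p = (1 + sum(null_counts >= observed)) / (n_perm + 1)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null: observed %d, null max %d over %d perms, p = %.4g>\n",
              x$observed_positive_count, max(x$null_counts), x$n_perm, x$empirical_p))
  invisible(x)
}

#' Null counts of a permutation test as a tibble
#'
#' @param x a `permutation_null`.
#' @param ... unused.
#' @return tibble with one row per permutation.
#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), positive_count = x$null_counts)
}

#' One-row summary of a permutation test
#'
#' @param x a `permutation_null`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble(observed_positive_count = x$observed_positive_count,
         null_max = max(x$null_counts), null_mean = mean(x$null_counts),
         n_perm = x$n_perm, empirical_p = x$empirical_p, seed = x$seed)
}

#' Leave-one-out scan for samples that disrupt the class structure
#'
#' Recomputes the number of positive delta-variances after removing each
#' sample in turn. Samples whose removal increases the count far above the
#' baseline are candidates for exclusion (they blur the class structure).
#'
#' @param cohort a `labeled_cohort` where each class keeps >= 2 samples
#'   after any single removal.
#' @return tibble with `sample_id`, `label`, `positive_count` (without that
#'   sample) and `baseline` (full-cohort count).
#' @export
sample_exclusion_scan <- function(cohort) {
  beta <- cohort$beta
  beta <- beta[rowSums(is.na(beta)) == 0, , drop = FALSE]
  sizes <- table(cohort$labels)
  if (any(sizes < 3)) abort("a class would drop below 2 samples during the scan")
  pos <- pos_idx(cohort)
  baseline <- sum(delta_for_labels(beta, pos) > 0)
  counts <- vapply(seq_len(ncol(beta)), function(i) {
    sub <- beta[, -i, drop = FALSE]
    p <- which(cohort$labels[-i] == "positive")
    sum(delta_for_labels(sub, p) > 0)
  }, integer(1))
  tibble(sample_id = colnames(beta), label = unname(cohort$labels),
         positive_count = counts, baseline = baseline)
}

#' Shadow-feature significance of selected probes
#'
#' For each repetition, every feature is duplicated as a "shadow" with its
#' values permuted across samples (destroying any label association while
#' preserving the marginal distribution), a forest is trained on real plus
#' shadow features, and a feature scores a miss when its importance does not
#' exceed the best shadow importance. The per-feature empirical p-value is
#' `(1 + misses) / (n_rep + 1)`.
#'
#' @param cohort a `labeled_cohort`.
#' @param features probe ids to score (subset of the matrix).
#' @param n_rep repetitions (>= 1).
#' @param seed integer seed.
#' @param params [rf_params()]; a reduced tree count is customary here.
#' @return tibble with `probe_id`, `mean_importance`, `p_value`.
#' @export
shadow_significance <- function(cohort, features, n_rep = 20, seed = 1,
                                params = rf_params(n_trees = 500)) {
  if (length(features) == 0) abort("empty feature list")
  missing_probes <- setdiff(features, rownames(cohort$beta))
  if (length(missing_probes) > 0) {
    abort(paste0("feature(s) not in matrix: ", paste(head(missing_probes, 3), collapse = ", ")))
  }
  if (n_rep < 1) abort("n_rep must be >= 1")
  x <- t(cohort$beta[features, , drop = FALSE])   # samples x features
  y <- cohort$labels
  seeds <- derive_seeds(seed, n_rep)
  misses <- numeric(length(features))
  imp_sum <- numeric(length(features))
  for (r in seq_len(n_rep)) {
    set.seed(seeds[r])
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("shadow_", colnames(x))
    xx <- cbind(x, shadow)
    fit <- fit_forest(xx, y, params, seed = seeds[r])
    imp <- randomForest::importance(fit, type = 2)[, 1]
    real_imp <- imp[colnames(x)]
    max_shadow <- max(imp[colnames(shadow)])
    misses <- misses + as.numeric(real_imp <= max_shadow)
    imp_sum <- imp_sum + real_imp
  }
  tibble(probe_id = features, mean_importance = imp_sum / n_rep,
         p_value = (1 + misses) / (n_rep + 1))
}
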