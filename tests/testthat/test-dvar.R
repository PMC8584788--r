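# Delta-variance statistic, ranking, decorrelation, permutation null,
# exclusion scan and shadow significance.

test_that("delta matches hand-computed n-1 variances", {
  m <- rbind(p1 = c(0.8, 0.8, 0.2, 0.2),   # pos {0.8, 0.8}, neg {0.2, 0.2}
             p2 = c(0.5, 0.5, 0.5, 0.5),
             p3 = c(0, 1, 0, 1))
  colnames(m) <- c("a", "b", "c", "d")
  cohort <- labeled_cohort(m, c("positive", "positive", "negative", "negative"))
  dv <- delta_variances(cohort)
  dv <- dv[match(c("p1", "p2", "p3"), dv$probe_id), ]
  expect_equal(dv$var_pos, c(0, 0, 0.5))
  expect_equal(dv$var_neg, c(0, 0, 0.5))
  expect_equal(dv$var_all, c(0.12, 0, 1 / 3))
  expect_equal(dv$delta, c(0.12, 0, 1 / 3 - 1))
  expect_equal(dv$rank, c(1, 2, 3))
})

test_that("delta agrees with the two-pass oracle to 1e-12 relative", {
  cohort <- make_cohort(n_probes = 200, n_pos = 7, n_neg = 5, seed = 9)
  dv <- delta_variances(cohort)
  for (i in sample(nrow(dv), 50)) {
    probe <- dv$probe_id[i]
    expected <- oracle_delta(cohort$beta[probe, ], cohort$labels)
    expect_equal(dv$delta[i], expected, tolerance = 1e-12)
  }
})

test_that("delta is invariant to sample order and symmetric in class swap", {
  cohort <- make_cohort(n_probes = 40, n_pos = 4, n_neg = 6, seed = 3)
  dv <- delta_variances(cohort)

  perm <- sample(ncol(cohort$beta))
  shuffled <- labeled_cohort(cohort$beta[, perm], cohort$labels[perm],
                             cohort$scores[perm])
  dv2 <- delta_variances(shuffled)
  expect_equal(dv2, dv)

  flipped_labels <- factor(ifelse(cohort$labels == "positive", "negative", "positive"),
                           levels = c("negative", "positive"))
  dv3 <- delta_variances(labeled_cohort(cohort$beta, flipped_labels))
  dv3 <- dv3[match(dv$probe_id, dv3$probe_id), ]
  expect_equal(dv3$delta, dv$delta)
  expect_equal(dv3$var_pos, dv$var_neg)
  expect_equal(dv3$var_neg, dv$var_pos)
})

test_that("classes below two samples are rejected", {
  m <- make_beta(5, 3)
  cohort <- labeled_cohort(m, c("positive", "negative", "negative"))
  expect_error(delta_variances(cohort), ">= 2 samples")
})

test_that("rank_top_k respects order, ties and overlong requests", {
  tab <- tibble::tibble(probe_id = c("a", "b", "c"), delta = c(0.3, 0.1, 0.2))
  tab$rank <- rank(order(order(-tab$delta, tab$probe_id)))
  expect_equal(rank_top_k(tab, 2), c("a", "c"))
  tie <- tibble::tibble(probe_id = c("b", "a"), delta = c(0.1, 0.1))
  tie$rank <- rank(order(order(-tie$delta, tie$probe_id)))
  expect_equal(rank_top_k(tie, 1), "a")
  expect_warning(all3 <- rank_top_k(tab, 10), "exceeds")
  expect_equal(all3, c("a", "c", "b"))
})

test_that("decorrelate keeps the greedy rho <= 0.8 subset", {
  # duplicated probe: the lower-ranked copy goes
  m <- make_beta(4, 10, seed = 5)
  m <- rbind(m, dup = m["cg0001", ])
  expect_equal(decorrelate(m, c("cg0001", "dup", "cg0002")),
               c("cg0001", "cg0002"))

  # constructed Pearson correlations: rho(a,b) = rho(b,c) = 0.9, rho(a,c) = 0.7
  target <- matrix(c(1, 0.9, 0.7, 0.9, 1, 0.9, 0.7, 0.9, 1), 3)
  set.seed(8)
  raw <- matrix(rnorm(3 * 30), nrow = 3)
  raw <- raw - rowMeans(raw)
  w <- solve(chol(tcrossprod(raw) / (30 - 1)))   # whiten exactly
  x <- crossprod(chol(target), t(w) %*% raw)
  rownames(x) <- c("a", "b", "c")
  colnames(x) <- sprintf("s%02d", 1:30)
  expect_equal(unname(cor(t(x))[1, 2]), 0.9, tolerance = 1e-9)
  expect_equal(decorrelate(x, c("a", "b", "c"), method = "pearson"), c("a", "c"))

  # all mutually uncorrelated probes are all retained
  low <- make_beta(6, 40, seed = 12)
  expect_equal(decorrelate(low, rownames(low)), rownames(low))

  # zero-variance probe is dropped with a warning
  const <- rbind(low, flat = rep(0.5, 40))
  expect_warning(kept <- decorrelate(const, rownames(const)), "zero-variance")
  expect_false("flat" %in% kept)
})

test_that("no retained pair exceeds rho_max and rank-1 survives (property)", {
  for (s in 1:10) {
    m <- make_beta(30, 12, seed = 100 + s)
    # add correlated blocks so the screen has work to do
    m[11:20, ] <- m[1:10, ] * 0.9 + m[11:20, ] * 0.1
    m <- pmin(pmax(m, 0), 1)
    ranked <- sample(rownames(m))
    kept <- decorrelate(m, ranked, rho_max = 0.8)
    expect_equal(kept[1], ranked[1])
    if (length(kept) > 1) {
      rho <- cor(t(apply(m[kept, ], 1, rank)))
      expect_true(all(abs(rho[upper.tri(rho)]) <= 0.8 + 1e-12))
    }
  }
})

test_that("permutation test separates planted structure from noise", {
  planted <- simulate_cohort(cohort_spec(n_pos = 12, n_neg = 10, n_probes = 400,
                                         n_informative = 40, seed = 21))
  pn <- suppressMessages(permute_class_structure(planted, n_perm = 199, seed = 5))
  expect_gt(pn$observed_positive_count, max(pn$null_counts))
  expect_equal(pn$empirical_p, 1 / 200)

  shuffled_labels <- sample(planted$labels)
  shuffled <- labeled_cohort(planted$beta, shuffled_labels)
  pn0 <- suppressMessages(permute_class_structure(shuffled, n_perm = 199, seed = 5))
  lo <- quantile(pn0$null_counts, 0.025)
  hi <- quantile(pn0$null_counts, 0.975)
  expect_gte(pn0$observed_positive_count, lo)
  expect_lte(pn0$observed_positive_count, hi)

  expect_error(permute_class_structure(planted, n_perm = 0), "n_perm")

  # bit-reproducible under a fixed seed
  pn2 <- suppressMessages(permute_class_structure(planted, n_perm = 199, seed = 5))
  expect_identical(pn2$null_counts, pn$null_counts)
  expect_true(pn$empirical_p > 0 && pn$empirical_p <= 1)
})

test_that("exclusion scan equals the definitional leave-one-out recomputation", {
  cohort <- make_cohort(n_probes = 80, n_pos = 5, n_neg = 4, seed = 31)
  scan <- sample_exclusion_scan(cohort)
  expect_equal(nrow(scan), 9)
  for (s in c("s01", "s06")) {
    rest <- setdiff(colnames(cohort$beta), s)
    sub <- labeled_cohort(cohort$beta[, rest], cohort$labels[rest])
    expected <- sum(delta_variances(sub)$delta > 0)
    expect_equal(scan$positive_count[scan$sample_id == s], expected)
  }
})

test_that("a planted disruptive sample gives the maximal count increase", {
  planted <- simulate_cohort(cohort_spec(n_pos = 10, n_neg = 8, n_probes = 300,
                                         n_informative = 60, seed = 41))
  inf <- attr(planted, "informative_probes")
  beta <- planted$beta
  # corrupt one positive sample: extreme values inflate var_pos at the
  # informative probes and blur the class structure
  beta[inf, "pos_003"] <- rep(c(0.02, 0.98), length.out = length(inf))
  corrupted <- labeled_cohort(beta, planted$labels, planted$scores)
  scan <- sample_exclusion_scan(corrupted)
  expect_equal(scan$sample_id[which.max(scan$positive_count)], "pos_003")
  expect_gt(max(scan$positive_count), scan$baseline[1])
})

test_that("shadow significance favors separating features and respects granularity", {
  planted <- simulate_cohort(cohort_spec(n_pos = 10, n_neg = 8, n_probes = 60,
                                         n_informative = 10, seed = 51))
  inf <- attr(planted, "informative_probes")
  noise <- setdiff(rownames(planted$beta), inf)[1:5]
  feats <- c(inf[1:5], noise)
  res <- shadow_significance(planted, feats, n_rep = 5, seed = 7,
                             params = rf_params(n_trees = 200))
  expect_lte(mean(res$p_value[res$probe_id %in% inf[1:5]]),
             mean(res$p_value[res$probe_id %in% noise]))

  one <- shadow_significance(planted, feats, n_rep = 1, seed = 7,
                             params = rf_params(n_trees = 100))
  expect_true(all(one$p_value %in% c(0.5, 1)))

  expect_error(shadow_significance(planted, "nope", n_rep = 1), "not in matrix")
  expect_error(shadow_significance(planted, character(0)), "empty")
})
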