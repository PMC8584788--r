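# Fixture builders shared across the suite.

# One segment row with defaults.
seg <- function(chrom, start, end, cn = 2L, cn_state = "neutral",
                allelic_state = "unknown", sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start, end = end,
                 copy_number = as.integer(cn), cn_state = cn_state,
                 allelic_state = allelic_state)
}

segs <- function(...) {
  out <- dplyr::bind_rows(...)
  if (nrow(out) == 0) out <- seg("chr1", 1, 1)[0, ]
  out
}

# Small beta matrix with deterministic content.
make_beta <- function(n_probes, n_samples, seed = 1,
                      probes = sprintf("cg%04d", seq_len(n_probes)),
                      samples = sprintf("s%02d", seq_len(n_samples))) {
  set.seed(seed)
  matrix(runif(n_probes * n_samples, 0.05, 0.95), nrow = n_probes,
         dimnames = list(probes, samples))
}

make_cohort <- function(n_probes = 50, n_pos = 5, n_neg = 5, seed = 1) {
  m <- make_beta(n_probes, n_pos + n_neg, seed = seed)
  labeled_cohort(m, rep(c("positive", "negative"), c(n_pos, n_neg)))
}

# Random segment genome over the real reference: random events of every
# class, including edge-case sizes straddling the thresholds, plus filler.
random_genome <- function(seed, ref = grch37_reference()) {
  set.seed(seed)
  rows <- list()
  chroms <- sample(ref$chrom, 8)
  for (ch in chroms) {
    len <- ref$length[match(ch, ref$chrom)]
    pos <- 1
    while (pos < len - 5e6) {
      w <- floor(runif(1, 1e6, 30e6))
      end <- min(pos + w - 1, len)
      cls <- sample(c("neutral", "gain", "loss", "loh", "ai"), 1,
                    prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
      rows[[length(rows) + 1]] <- switch(cls,
        neutral = seg(ch, pos, end),
        gain = seg(ch, pos, end, cn = 3, cn_state = "gain"),
        loss = seg(ch, pos, end, cn = 1, cn_state = "loss"),
        loh = seg(ch, pos, end, allelic_state = "LOH"),
        ai = seg(ch, pos, end, allelic_state = "AI"))
      pos <- end + 1 + floor(runif(1, 0, 8e6))   # sometimes adjacent, sometimes gapped
    }
  }
  # occasionally a whole-chromosome LOH
  if (runif(1) < 0.3) {
    ch <- sample(setdiff(ref$chrom, chroms), 1)
    rows[[length(rows) + 1]] <-
      seg(ch, 1, ref$length[match(ch, ref$chrom)], allelic_state = "LOH")
  }
  dplyr::bind_rows(rows)
}

expect_scores_match_oracle <- function(genome, ref = grch37_reference()) {
  expect_identical(hrd_loh(genome, ref), oracle_hrd_loh(genome, ref))
  expect_identical(hrd_loh(genome, ref, exclude_whole_chromosome = FALSE),
                   oracle_hrd_loh(genome, ref, exclude_whole_chromosome = FALSE))
  expect_identical(hrd_tai(genome, ref), oracle_hrd_tai(genome, ref))
  expect_identical(hrd_lst(genome, ref), oracle_hrd_lst(genome, ref))
  expect_identical(hrd_lst(genome, ref, per_arm = FALSE),
                   oracle_hrd_lst(genome, ref, per_arm = FALSE))
  expect_equal(pgc_nexus(genome, ref), oracle_pgc_nexus(genome, ref))
  expect_equal(pgc_freec(genome, ref), oracle_pgc_freec(genome, ref))
}
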