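# Internal numeric helpers.

# Row-wise sample variance (denominator n - 1), computed from centered
# residuals so near-constant rows do not lose precision to cancellation.
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) abort("variance needs >= 2 samples")
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Rank-transform each row (average ranks for ties), for Spearman correlation.
row_ranks <- function(m) {
  t(apply(m, 1, rank))
}

# Derive a stream of distinct 31-bit seeds from one user seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
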