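# Independent brute-force oracles. These re-derive every score with plain
# loops and explicit rules, sharing no code with the package internals.

MB_ <- 1e6

o_autosomes <- function(ref) setdiff(ref$chrom, attr(ref, "sex_chromosomes"))

o_chr <- function(ref, chrom) as.list(ref[match(chrom, ref$chrom), ])

oracle_hrd_loh <- function(segments, ref, exclude_whole_chromosome = TRUE) {
  count <- 0L
  cols <- as.list(segments)
  for (i in seq_len(nrow(segments))) {
    row <- lapply(cols, `[`, i)
    if (!(row$chrom %in% o_autosomes(ref))) next
    if (row$allelic_state != "LOH") next
    w <- row$end - row$start + 1
    if (w <= 15 * MB_) next
    if (exclude_whole_chromosome &&
        row$start == 1 && row$end == o_chr(ref, row$chrom)$length) next
    count <- count + 1L
  }
  count
}

oracle_hrd_tai <- function(segments, ref, terminus_tolerance = 0) {
  count <- 0L
  cols <- as.list(segments)
  for (i in seq_len(nrow(segments))) {
    row <- lapply(cols, `[`, i)
    if (!(row$chrom %in% o_autosomes(ref))) next
    if (row$allelic_state != "AI") next
    info <- o_chr(ref, row$chrom)
    w <- row$end - row$start + 1
    if (w <= 11 * MB_) next
    touches <- row$start <= terminus_tolerance + 1 ||
      row$end >= info$length - terminus_tolerance
    if (!touches) next
    overlaps_cen <- row$start <= info$cen_end && row$end >= info$cen_start
    if (overlaps_cen) next
    count <- count + 1L
  }
  count
}

# LST oracle: clip to arms (or whole chromosomes), drop < 3 Mb, merge
# identical-state neighbours within a 3 Mb gap, then scan adjacent pairs.
oracle_hrd_lst <- function(segments, ref, per_arm = TRUE) {
  total <- 0L
  for (ch in intersect(unique(segments$chrom), o_autosomes(ref))) {
    info <- o_chr(ref, ch)
    s <- segments[segments$chrom == ch, ]
    units <- if (per_arm) {
      list(c(1, info$cen_start - 1), c(info$cen_end + 1, info$length))
    } else {
      list(c(1, info$length))
    }
    for (u in units) {
      pieces <- list()
      for (i in seq_len(nrow(s))) {
        a <- max(s$start[i], u[1]); b <- min(s$end[i], u[2])
        if (b < a) next
        pieces[[length(pieces) + 1]] <-
          list(start = a, end = b, state = paste(s$copy_number[i], s$cn_state[i]))
      }
      pieces <- Filter(function(p) (p$end - p$start + 1) >= 3 * MB_, pieces)
      if (length(pieces) < 2) next
      pieces <- pieces[order(vapply(pieces, `[[`, numeric(1), "start"))]
      merged <- list(pieces[[1]])
      for (p in pieces[-1]) {
        last <- merged[[length(merged)]]
        if (p$state == last$state && (p$start - last$end - 1) <= 3 * MB_) {
          merged[[length(merged)]]$end <- p$end
        } else {
          merged[[length(merged) + 1]] <- p
        }
      }
      if (length(merged) < 2) next
      for (j in seq_len(length(merged) - 1)) {
        a <- merged[[j]]; b <- merged[[j + 1]]
        wa <- a$end - a$start + 1; wb <- b$end - b$start + 1
        gap <- b$start - a$end - 1
        if (wa >= 10 * MB_ && wb >= 10 * MB_ && gap <= 3 * MB_ && a$state != b$state) {
          total <- total + 1L
        }
      }
    }
  }
  total
}

oracle_pgc_nexus <- function(segments, ref) {
  covered <- 0
  cols <- as.list(segments)
  for (i in seq_len(nrow(segments))) {
    row <- lapply(cols, `[`, i)
    if (!(row$chrom %in% o_autosomes(ref))) next
    if (!(row$cn_state %in% c("gain", "loss"))) next
    w <- row$end - row$start + 1
    if (w >= 10 * MB_) covered <- covered + w
  }
  100 * covered / attr(ref, "haploid_length")
}

oracle_pgc_freec <- function(segments, ref, terminus_tolerance = 0) {
  covered <- 0
  cols <- as.list(segments)
  for (i in seq_len(nrow(segments))) {
    row <- lapply(cols, `[`, i)
    if (!(row$chrom %in% o_autosomes(ref))) next
    info <- o_chr(ref, row$chrom)
    w <- row$end - row$start + 1
    if (row$cn_state %in% c("gain", "loss") && w >= 10 * MB_) covered <- covered + w
    if (row$allelic_state == "LOH" && w > 15 * MB_) covered <- covered + w
    if (row$allelic_state == "AI" && w > 11 * MB_ &&
        (row$start <= terminus_tolerance + 1 ||
           row$end >= info$length - terminus_tolerance) &&
        !(row$start <= info$cen_end && row$end >= info$cen_start)) {
      covered <- covered + w
    }
  }
  100 * covered / attr(ref, "haploid_length")
}

# Two-pass delta-variance oracle: explicit mean then explicit SSE.
oracle_delta <- function(values, labels) {
  vv <- function(x) {
    m <- sum(x) / length(x)
    sse <- 0
    for (xi in x) sse <- sse + (xi - m)^2
    sse / (length(x) - 1)
  }
  vv(values) - vv(values[labels == "positive"]) - vv(values[labels == "negative"])
}

# Literal position-by-position running-sum enrichment oracle with
# first-occurrence tie-break; integer hit/miss counters keep each value
# exact so agreement with a closed-form implementation is bitwise.
oracle_es <- function(genes, set) {
  n <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  hits <- 0L; misses <- 0L
  best <- 0
  for (j in seq_len(n)) {
    if (hit[j]) hits <- hits + 1L else misses <- misses + 1L
    value <- hits / nh - misses / (n - nh)
    if (abs(value) > abs(best)) best <- value
  }
  best
}

# Mann-Whitney pair-counting AUC (ties count one half).
oracle_auc <- function(votes, labels) {
  pos <- votes[labels == "positive"]
  neg <- votes[labels == "negative"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive-search concordance-maximizing cutoff (strict > rule).
oracle_calibrate <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(s[1] - 0.5, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
             s[length(s)] + 0.5)
  best <- -Inf; best_c <- NA
  for (c0 in cands) {
    conc <- sum((scores > c0) == (labels == "positive"))
    if (conc > best) { best <- conc; best_c <- c0 }
  }
  best_c
}
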