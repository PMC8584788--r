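# Genomic-scar scores: HRD-LOH, HRD-TAI, HRD-LST, and the two
# percent-of-genome-changed (PGC) variants, plus BRCAness labeling.

MB <- 1e6

one_sample <- function(segments) {
  ids <- unique(segments$sample_id)
  if (length(ids) > 1) {
    abort(paste0("expected segments of a single sample, got: ",
                 paste(ids, collapse = ", ")))
  }
  invisible(ids)
}

#' HRD-LOH: count of long loss-of-heterozygosity regions
#'
#' Counts autosomal segments with `allelic_state == "LOH"` strictly longer
#' than 15 Mb. By convention, LOH spanning a whole chromosome is excluded
#' (controlled by `exclude_whole_chromosome`).
#'
#' @param segments segment tibble of a single sample.
#' @param ref a [genome_reference()].
#' @param exclude_whole_chromosome drop LOH segments that cover an entire
#'   chromosome (`start == 1` and `end == ` chromosome length)?
#' @return integer count.
#' @export
hrd_loh <- function(segments, ref, exclude_whole_chromosome = TRUE) {
  one_sample(segments)
  s <- segments[segments$allelic_state == "LOH" &
                  segments$chrom %in% autosomes(ref), , drop = FALSE]
  if (nrow(s) == 0) return(0L)
  keep <- seg_width(s) > 15 * MB
  if (exclude_whole_chromosome) {
    whole <- s$start == 1 & s$end == ref_lookup(ref, s$chrom, "length")
    keep <- keep & !whole
  }
  sum(keep)
}

#' HRD-TAI: count of long subtelomeric allelic-imbalance regions
#'
#' Counts autosomal segments with `allelic_state == "AI"` strictly longer
#' than 11 Mb that extend to a chromosome terminus (within
#' `terminus_tolerance` bases) and do not overlap the centromere interval.
#'
#' @inheritParams hrd_loh
#' @param terminus_tolerance maximal distance (bp) between the segment
#'   boundary and the chromosome terminus still counted as subtelomeric.
#' @return integer count.
#' @export
hrd_tai <- function(segments, ref, terminus_tolerance = 0) {
  one_sample(segments)
  s <- segments[segments$allelic_state == "AI" &
                  segments$chrom %in% autosomes(ref), , drop = FALSE]
  if (nrow(s) == 0) return(0L)
  len <- ref_lookup(ref, s$chrom, "length")
  cen_start <- ref_lookup(ref, s$chrom, "cen_start")
  cen_end <- ref_lookup(ref, s$chrom, "cen_end")
  if (anyNA(cen_start) || anyNA(cen_end)) {
    abort("missing centromere interval for a chromosome with AI segments")
  }
  long_enough <- seg_width(s) > 11 * MB
  subtelomeric <- s$start <= terminus_tolerance + 1 | s$end >= len - terminus_tolerance
  crosses_cen <- s$start <= cen_end & s$end >= cen_start
  sum(long_enough & subtelomeric & !crosses_cen)
}

# Split segments at the centromere into per-arm pieces (the part inside the
# centromere interval is discarded). Returns segments with an `arm` column.
split_by_arm <- function(s, ref) {
  cen_start <- ref_lookup(ref, s$chrom, "cen_start")
  cen_end <- ref_lookup(ref, s$chrom, "cen_end")
  p <- s
  p$end <- pmin(p$end, cen_start - 1)
  p$arm <- "p"
  q <- s
  q$start <- pmax(q$start, cen_end + 1)
  q$arm <- "q"
  out <- dplyr::bind_rows(p, q)
  out[out$end >= out$start, , drop = FALSE]
}

# Shared LST core: filter < 3 Mb, merge identical-state neighbours within a
# <= 3 Mb gap, count state changes between >= 10 Mb flanks within a <= 3 Mb gap.
lst_breakpoints_1d <- function(start, end, state) {
  keep <- (end - start + 1) >= 3 * MB
  start <- start[keep]; end <- end[keep]; state <- state[keep]
  if (length(start) < 2) return(0L)
  o <- order(start)
  start <- start[o]; end <- end[o]; state <- state[o]
  # merge runs of identical state whose gaps are <= 3 Mb
  ms <- start[1]; me <- end[1]; mstate <- state[1]
  m_start <- numeric(0); m_end <- numeric(0); m_state <- character(0)
  for (i in seq_along(start)[-1]) {
    gap <- start[i] - me - 1
    if (identical(state[i], mstate) && gap <= 3 * MB) {
      me <- end[i]
    } else {
      m_start <- c(m_start, ms); m_end <- c(m_end, me); m_state <- c(m_state, mstate)
      ms <- start[i]; me <- end[i]; mstate <- state[i]
    }
  }
  m_start <- c(m_start, ms); m_end <- c(m_end, me); m_state <- c(m_state, mstate)
  if (length(m_start) < 2) return(0L)
  w <- m_end - m_start + 1
  gap <- m_start[-1] - m_end[-length(m_end)] - 1
  sum(gap <= 3 * MB &
        w[-length(w)] >= 10 * MB & w[-1] >= 10 * MB &
        m_state[-1] != m_state[-length(m_state)])
}

#' HRD-LST: count of large-scale state transitions
#'
#' After discarding segments shorter than 3 Mb and merging neighbouring
#' segments of identical copy-number state, counts breakpoints between
#' adjacent merged regions that are both at least 10 Mb long, differ in
#' state, and lie within 3 Mb of each other (the smoothing allowance of the
#' original large-scale-transition definition). Computed per chromosome arm
#' by default; segments straddling the centromere are split at it.
#'
#' The ploidy-adjusted LST positivity cutoff used by some assays is not
#' applied; the raw transition count is returned.
#'
#' @inheritParams hrd_loh
#' @param per_arm compute transitions per chromosome arm (default) rather
#'   than per whole chromosome.
#' @return integer count.
#' @export
hrd_lst <- function(segments, ref, per_arm = TRUE) {
  one_sample(segments)
  s <- segments[segments$chrom %in% autosomes(ref), , drop = FALSE]
  if (nrow(s) == 0) return(0L)
  check_no_overlap(s)
  state <- paste(s$copy_number, s$cn_state)
  s$state <- state
  if (per_arm) {
    s <- split_by_arm(s, ref)
    groups <- split(s, paste(s$chrom, s$arm))
  } else {
    groups <- split(s, s$chrom)
  }
  total <- 0L
  for (g in groups) {
    total <- total + lst_breakpoints_1d(g$start, g$end, g$state)
  }
  total
}

#' PGC, NexusCN variant: percent of genome covered by long copy-number calls
#'
#' Sums the widths of autosomal gain and loss segments at least 10 Mb wide
#' (allelic-imbalance and LOH calls are ignored) and divides by the haploid
#' genome length, as a percent.
#'
#' @inheritParams hrd_loh
#' @return percent (numeric).
#' @export
pgc_nexus <- function(segments, ref) {
  one_sample(segments)
  s <- segments[segments$cn_state %in% c("gain", "loss") &
                  segments$chrom %in% autosomes(ref), , drop = FALSE]
  if (nrow(s) == 0) return(0)
  w <- seg_width(s)
  100 * sum(w[w >= 10 * MB]) / attr(ref, "haploid_length")
}

#' PGC, FREEC/HRDtools variant: percent of genome covered by scar-qualifying calls
#'
#' Sums the widths of qualifying events -- copy-number alterations (gain or
#' loss) at least 10 Mb wide, allelic-imbalance segments qualifying for
#' HRD-TAI (longer than 11 Mb, subtelomeric, not crossing the centromere),
#' and LOH segments longer than 15 Mb -- and divides by the haploid genome
#' length, as a percent. Widths are summed as emitted: an interval called
#' both as a CNA and as LOH is counted twice, so the value can exceed 100 on
#' pathological input.
#'
#' @inheritParams hrd_tai
#' @return percent (numeric).
#' @export
pgc_freec <- function(segments, ref, terminus_tolerance = 0) {
  one_sample(segments)
  auto <- segments[segments$chrom %in% autosomes(ref), , drop = FALSE]
  if (nrow(auto) == 0) return(0)
  w <- seg_width(auto)

  cna <- auto$cn_state %in% c("gain", "loss") & w >= 10 * MB
  loh <- auto$allelic_state == "LOH" & w > 15 * MB

  len <- ref_lookup(ref, auto$chrom, "length")
  cen_start <- ref_lookup(ref, auto$chrom, "cen_start")
  cen_end <- ref_lookup(ref, auto$chrom, "cen_end")
  tai <- auto$allelic_state == "AI" & w > 11 * MB &
    (auto$start <= terminus_tolerance + 1 | auto$end >= len - terminus_tolerance) &
    !(auto$start <= cen_end & auto$end >= cen_start)

  100 * (sum(w[cna]) + sum(w[tai]) + sum(w[loh])) / attr(ref, "haploid_length")
}

#' Threshold schemes for BRCAness labeling
#'
#' Three named schemes with their published cutoffs: the HRD sum
#' (LOH + TAI + LST, positive at `>= 42`), the NexusCN PGC (positive at
#' `> 32`) and the FREEC/HRDtools PGC (positive at `> 28`).
#'
#' @param name `"HRD"`, `"PGC_NEXUS"` or `"PGC_FREEC"`.
#' @param cutoff override the default cutoff.
#' @param comparison override the default comparison (`">="` or `">"`).
#' @return a `threshold_scheme` list with `name`, `cutoff`, `comparison`.
#' @examples
#' threshold_scheme("PGC_NEXUS")
#' @export
threshold_scheme <- function(name = c("HRD", "PGC_NEXUS", "PGC_FREEC"),
                             cutoff = NULL, comparison = NULL) {
  name <- match.arg(name)
  defaults <- list(HRD = list(cutoff = 42, comparison = ">="),
                   PGC_NEXUS = list(cutoff = 32, comparison = ">"),
                   PGC_FREEC = list(cutoff = 28, comparison = ">"))
  cutoff <- cutoff %||% defaults[[name]]$cutoff
  comparison <- comparison %||% defaults[[name]]$comparison
  if (!comparison %in% c(">=", ">")) abort("comparison must be \">=\" or \">\"")
  if (!is.finite(cutoff)) abort("cutoff must be finite")
  structure(list(name = name, cutoff = cutoff, comparison = comparison),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf("<threshold_scheme %s: positive iff score %s %g>\n",
              x$name, x$comparison, x$cutoff))
  invisible(x)
}

#' Label samples as BRCAness-positive or -negative by threshold
#'
#' @param score numeric vector of scores (HRD sums or PGC percents).
#' @param scheme a [threshold_scheme()].
#' @return factor with levels `negative`, `positive`.
#' @examples
#' label_brcaness(c(41, 42, 43), threshold_scheme("HRD"))
#' @export
label_brcaness <- function(score, scheme) {
  if (!inherits(scheme, "threshold_scheme")) abort("scheme must be a threshold_scheme")
  if (any(!is.finite(score))) abort("scores must be finite")
  pos <- if (scheme$comparison == ">=") score >= scheme$cutoff else score > scheme$cutoff
  factor(ifelse(pos, "positive", "negative"), levels = c("negative", "positive"))
}

#' Score every sample in a segment table
#'
#' Computes HRD-LOH, HRD-TAI, HRD-LST, their sum, both PGC variants, and the
#' BRCAness label under the chosen scheme, one row per sample.
#'
#' @param segments segment tibble (any number of samples).
#' @param ref a [genome_reference()].
#' @param scheme a [threshold_scheme()] deciding which score is thresholded
#'   into the label.
#' @inheritParams hrd_loh
#' @inheritParams hrd_tai
#' @inheritParams hrd_lst
#' @return tibble with columns `sample_id`, `loh_count`, `tai_count`,
#'   `lst_count`, `hrd_sum`, `pgc_nexus`, `pgc_freec`, `score`, `label`,
#'   `scheme_used`.
#' @export
scar_scores <- function(segments, ref, scheme = threshold_scheme("HRD"),
                        exclude_whole_chromosome = TRUE,
                        terminus_tolerance = 0, per_arm = TRUE) {
  inform("LST counts are raw transition counts; no ploidy-adjusted cutoff is applied.",
         .frequency = "once", .frequency_id = "brcaness_lst_ploidy_note")
  samples <- unique(segments$sample_id)
  rows <- purrr::map(samples, function(id) {
    s <- segments[segments$sample_id == id, , drop = FALSE]
    loh <- hrd_loh(s, ref, exclude_whole_chromosome = exclude_whole_chromosome)
    tai <- hrd_tai(s, ref, terminus_tolerance = terminus_tolerance)
    lst <- hrd_lst(s, ref, per_arm = per_arm)
    tibble(sample_id = id, loh_count = loh, tai_count = tai, lst_count = lst,
           hrd_sum = loh + tai + lst,
           pgc_nexus = pgc_nexus(s, ref),
           pgc_freec = pgc_freec(s, ref, terminus_tolerance = terminus_tolerance))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(), loh_count = integer(),
                  tai_count = integer(), lst_count = integer(),
                  hrd_sum = integer(), pgc_nexus = numeric(),
                  pgc_freec = numeric())
  }
  out$score <- switch(scheme$name,
                      HRD = as.numeric(out$hrd_sum),
                      PGC_NEXUS = out$pgc_nexus,
                      PGC_FREEC = out$pgc_freec)
  out$label <- label_brcaness(out$score, scheme)
  out$scheme_used <- scheme$name
  out
}

#' Calibrate a threshold on new scores against reference labels
#'
#' Exhaustively evaluates cutoffs (midpoints between consecutive distinct
#' scores, plus sentinels below and above the observed range) under the
#' strict `score > cutoff` rule and returns the cutoff maximizing label
#' concordance; ties go to the smallest such cutoff.
#'
#' @param scores_new numeric scores on the new scale.
#' @param labels_ref reference labels, coercible to
#'   factor(levels = c("negative", "positive")).
#' @return the calibrated cutoff (numeric scalar).
#' @export
calibrate_threshold <- function(scores_new, labels_ref) {
  labels_ref <- factor(as.character(labels_ref), levels = c("negative", "positive"))
  if (length(scores_new) != length(labels_ref)) {
    abort("scores_new and labels_ref must have equal length")
  }
  if (anyNA(labels_ref)) abort("labels must be 'positive' or 'negative'")
  if (length(unique(labels_ref)) < 2) {
    abort("reference labels contain a single class; cannot calibrate")
  }
  s <- sort(unique(scores_new))
  if (length(s) == 1) {
    warn("all scores identical; concordance cannot exceed the majority class")
    candidates <- c(s - 0.5, s + 0.5)
  } else {
    candidates <- c(s[1] - 0.5, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 0.5)
  }
  concord <- vapply(candidates, function(c0) {
    sum((scores_new > c0) == (labels_ref == "positive"))
  }, numeric(1))
  candidates[which.max(concord)]  # which.max takes the first, i.e. smallest
}
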