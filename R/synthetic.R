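# Seeded synthetic-data generators: methylation cohorts with planted
# group-dependent probes, segment tables with planted scar events, and
# differential-expression tables with planted enriched gene sets.

#' Specification of a synthetic methylation cohort
#'
#' Defaults emulate the structure the classifier assumes: a minority of
#' informative probes whose mean beta is shifted downwards (hypomethylated)
#' and whose variance is inflated in the BRCAness-positive class, on top of
#' exchangeable background probes; class sizes default to 26 positive and
#' 17 negative. Beta values are drawn from Beta distributions parameterized
#' by (mean, concentration) so the support stays in \[0, 1\] and spread can
#' be inflated independently of the mean.
#'
#' @param n_pos,n_neg class sizes.
#' @param n_probes total probes.
#' @param n_informative probes carrying group structure (<= `n_probes`).
#' @param base_mean_beta negative-class mean beta of informative probes.
#' @param informative_shift decrease of the positive-class mean beta.
#' @param informative_spread_factor positive-class variance inflation
#'   (divides the Beta concentration).
#' @param noise_concentration Beta concentration of background noise (larger
#'   means tighter probes).
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_pos = 26, n_neg = 17, n_probes = 5000,
                        n_informative = 100, base_mean_beta = 0.6,
                        informative_shift = 0.3,
                        informative_spread_factor = 2,
                        noise_concentration = 100, seed = 1) {
  if (n_informative > n_probes) abort("n_informative must be <= n_probes")
  if (informative_spread_factor <= 0 || noise_concentration <= 0) {
    abort("spread factor and concentration must be positive")
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, n_probes = n_probes,
                 n_informative = n_informative, base_mean_beta = base_mean_beta,
                 informative_shift = informative_shift,
                 informative_spread_factor = informative_spread_factor,
                 noise_concentration = noise_concentration, seed = seed),
            class = "cohort_spec")
}

rbeta_mc <- function(n, mean, concentration) {
  rbeta(n, shape1 = mean * concentration, shape2 = (1 - mean) * concentration)
}

#' Simulate a labeled methylation cohort
#'
#' Background probes are drawn identically for both classes; informative
#' probes get a lower mean and inflated spread in the positive class. The
#' result is a pure function of the spec (including its seed). The planted
#' probe ids are attached as attribute `"informative_probes"`, and per-sample
#' scores compatible with the NexusCN PGC scheme (positives above 32,
#' negatives below) are attached so ranking operations behave naturally.
#'
#' @param spec a [cohort_spec()].
#' @return a `labeled_cohort`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mu_pos_low <- spec$base_mean_beta - 0.05 - spec$informative_shift
  if (spec$n_informative > 0 &&
      (mu_pos_low < 0.02 || spec$base_mean_beta + 0.05 > 0.98)) {
    abort("infeasible spec: informative_shift pushes means outside (0, 1)")
  }
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  probes <- sprintf("cg%06d", seq_len(spec$n_probes))
  samples <- c(sprintf("pos_%03d", seq_len(spec$n_pos)),
               sprintf("neg_%03d", seq_len(spec$n_neg)))
  labels <- rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg))
  informative <- sort(sample(spec$n_probes, spec$n_informative))

  mu_bg <- runif(spec$n_probes, 0.15, 0.85)
  m <- matrix(rbeta_mc(spec$n_probes * n, rep(mu_bg, n), spec$noise_concentration),
              nrow = spec$n_probes, ncol = n,
              dimnames = list(probes, samples))
  if (spec$n_informative > 0) {
    k <- spec$n_informative
    mu_neg <- runif(k, spec$base_mean_beta - 0.05, spec$base_mean_beta + 0.05)
    mu_pos <- mu_neg - spec$informative_shift
    m[informative, seq_len(spec$n_pos)] <-
      rbeta_mc(k * spec$n_pos, rep(mu_pos, spec$n_pos),
               spec$noise_concentration / spec$informative_spread_factor)
    m[informative, spec$n_pos + seq_len(spec$n_neg)] <-
      rbeta_mc(k * spec$n_neg, rep(mu_neg, spec$n_neg), spec$noise_concentration)
  }
  scores <- c(runif(spec$n_pos, 33, 90), runif(spec$n_neg, 1, 31))
  names(scores) <- samples
  cohort <- labeled_cohort(m, labels, scores, threshold_scheme("PGC_NEXUS"))
  attr(cohort, "informative_probes") <- probes[informative]
  cohort
}

#' Specification of planted genomic-scar events
#'
#' Requested counts of qualifying events per class; sizes (bp) are sampled
#' uniformly within ranges that respect each class's length threshold
#' (LOH > 15 Mb, TAI > 11 Mb, LST flanks >= 10 Mb, CNA >= 10 Mb). LST events
#' are planted as a neutral flank adjacent to a gain flank, optionally
#' separated by a sub-3 Mb spacer, so each contributes exactly one
#' transition; the gain flank also counts toward both PGC variants (the
#' recorded ground truth accounts for this).
#'
#' @param loh,tai,lst,gain,loss planted qualifying event counts.
#' @param loh_size,tai_size,lst_region_size,cna_size bp size ranges
#'   (length-2 numeric).
#' @param chromosomes chromosomes available for placement.
#' @param filler_width width of the neutral filler chunks completing each
#'   chromosome; must stay under the 3 Mb smoothing threshold.
#' @param seed integer seed.
#' @return a `scar_spec` list.
#' @export
scar_spec <- function(loh = 0, tai = 0, lst = 0, gain = 0, loss = 0,
                      loh_size = c(16e6, 25e6), tai_size = c(12e6, 20e6),
                      lst_region_size = c(10e6, 15e6), cna_size = c(10e6, 20e6),
                      chromosomes = paste0("chr", 1:22),
                      filler_width = 2.5e6, seed = 1) {
  if (loh_size[1] <= 15e6) abort("loh_size must exceed 15 Mb")
  if (tai_size[1] <= 11e6) abort("tai_size must exceed 11 Mb")
  if (lst_region_size[1] < 10e6) abort("lst_region_size must be >= 10 Mb")
  if (cna_size[1] < 10e6) abort("cna_size must be >= 10 Mb")
  if (filler_width >= 3e6) abort("filler_width must stay below 3 Mb")
  structure(list(loh = loh, tai = tai, lst = lst, gain = gain, loss = loss,
                 loh_size = loh_size, tai_size = tai_size,
                 lst_region_size = lst_region_size, cna_size = cna_size,
                 chromosomes = chromosomes, filler_width = filler_width,
                 seed = seed),
            class = "scar_spec")
}

# Buffer of event-free space (> 3 Mb) that isolates planted events from each
# other so no unplanned large-scale transitions arise.
.EVENT_BUFFER <- 4e6

#' Simulate a segment table with planted scar events
#'
#' Places the requested events on chromosome arms with > 3 Mb buffers
#' between them, then completes every chromosome with sub-3 Mb neutral
#' filler segments. The exact expected scores (event counts and both PGC
#' percents, including the PGC contribution of LST gain flanks and of
#' TAI/LOH events to the FREEC variant) are recorded at placement time in
#' attribute `"truth"`.
#'
#' @param spec a [scar_spec()].
#' @param ref a [genome_reference()] (default [grch37_reference()]).
#' @param sample_id sample name for the generated table.
#' @return a segment tibble with attribute `"truth"`.
#' @export
simulate_segments <- function(spec, ref = grch37_reference(),
                              sample_id = "synthetic_01") {
  stopifnot(inherits(spec, "scar_spec"))
  set.seed(spec$seed)
  chroms <- intersect(spec$chromosomes, ref$chrom)
  if (length(chroms) == 0) abort("no requested chromosome is in the reference")

  arms <- dplyr::bind_rows(lapply(chroms, function(ch) {
    i <- match(ch, ref$chrom)
    tibble(chrom = ch,
           arm = c("p", "q"),
           lo = c(1, ref$cen_end[i] + 1),
           hi = c(ref$cen_start[i] - 1, ref$length[i]))
  }))
  arms <- arms[sample.int(nrow(arms)), , drop = FALSE]

  segs <- list()
  truth_w <- list(gain = 0, loss = 0, tai = 0, loh = 0)
  add_seg <- function(start, end, cn, cn_state, allelic_state, chrom) {
    segs[[length(segs) + 1]] <<- tibble(
      sample_id = sample_id, chrom = chrom, start = start, end = end,
      copy_number = cn, cn_state = cn_state, allelic_state = allelic_state)
  }
  rwidth <- function(range) floor(runif(1, range[1], range[2]))

  # TAI events claim an arm terminus each (p-arm start or q-arm end).
  tai_armed <- 0
  for (a in seq_len(nrow(arms))) {
    if (tai_armed >= spec$tai) break
    w <- rwidth(spec$tai_size)
    if (w + .EVENT_BUFFER > arms$hi[a] - arms$lo[a] + 1) next
    if (arms$arm[a] == "p") {
      add_seg(arms$lo[a], arms$lo[a] + w - 1, 2L, "neutral", "AI", arms$chrom[a])
      arms$lo[a] <- arms$lo[a] + w + .EVENT_BUFFER
    } else {
      add_seg(arms$hi[a] - w + 1, arms$hi[a], 2L, "neutral", "AI", arms$chrom[a])
      arms$hi[a] <- arms$hi[a] - w - .EVENT_BUFFER
    }
    truth_w$tai <- truth_w$tai + w
    tai_armed <- tai_armed + 1
  }
  if (tai_armed < spec$tai) abort("chromosomes too small for the requested TAI events")

  place <- function(widths) {
    total <- sum(widths)
    fit <- which(arms$hi - arms$lo + 1 >= total + .EVENT_BUFFER)
    if (length(fit) == 0) abort("chromosomes too small for the requested events")
    a <- fit[which.max(arms$hi[fit] - arms$lo[fit])]
    starts <- arms$lo[a] + cumsum(c(0, widths[-length(widths)]))
    arms$lo[a] <<- arms$lo[a] + total + .EVENT_BUFFER
    list(chrom = arms$chrom[a], starts = starts, ends = starts + widths - 1)
  }

  for (i in seq_len(spec$lst)) {
    w1 <- rwidth(spec$lst_region_size)
    w2 <- rwidth(spec$lst_region_size)
    spacer <- if (runif(1) < 0.5) floor(runif(1, 5e5, 2.9e6)) else 0
    widths <- if (spacer > 0) c(w1, spacer, w2) else c(w1, w2)
    p <- place(widths)
    add_seg(p$starts[1], p$ends[1], 2L, "neutral", "balanced", p$chrom)
    if (spacer > 0) add_seg(p$starts[2], p$ends[2], 2L, "neutral", "balanced", p$chrom)
    j <- length(widths)
    add_seg(p$starts[j], p$ends[j], 3L, "gain", "unknown", p$chrom)
    truth_w$gain <- truth_w$gain + w2
  }
  for (i in seq_len(spec$loh)) {
    w <- rwidth(spec$loh_size)
    p <- place(w)
    add_seg(p$starts, p$ends, 2L, "neutral", "LOH", p$chrom)
    truth_w$loh <- truth_w$loh + w
  }
  for (i in seq_len(spec$gain)) {
    w <- rwidth(spec$cna_size)
    p <- place(w)
    add_seg(p$starts, p$ends, 3L, "gain", "unknown", p$chrom)
    truth_w$gain <- truth_w$gain + w
  }
  for (i in seq_len(spec$loss)) {
    w <- rwidth(spec$cna_size)
    p <- place(w)
    add_seg(p$starts, p$ends, 1L, "loss", "unknown", p$chrom)
    truth_w$loss <- truth_w$loss + w
  }

  events <- if (length(segs) > 0) dplyr::bind_rows(segs) else
    tibble(sample_id = character(), chrom = character(), start = numeric(),
           end = numeric(), copy_number = integer(), cn_state = character(),
           allelic_state = character())

  # complete each chromosome with sub-3 Mb neutral filler chunks
  filler <- list()
  for (ch in chroms) {
    len <- ref$length[match(ch, ref$chrom)]
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    gaps_lo <- c(1, ev$end + 1)
    gaps_hi <- c(ev$start - 1, len)
    for (g in seq_along(gaps_lo)) {
      if (gaps_hi[g] < gaps_lo[g]) next
      w <- gaps_hi[g] - gaps_lo[g] + 1
      n_chunks <- ceiling(w / spec$filler_width)
      bounds <- gaps_lo[g] + floor(w * seq(0, n_chunks) / n_chunks)
      filler[[length(filler) + 1]] <- tibble(
        sample_id = sample_id, chrom = ch,
        start = bounds[-length(bounds)], end = bounds[-1] - 1,
        copy_number = 2L, cn_state = "neutral", allelic_state = "balanced")
    }
  }
  out <- dplyr::bind_rows(events, dplyr::bind_rows(filler))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- segment_table(out, ref = ref)

  hl <- attr(ref, "haploid_length")
  cna_w <- truth_w$gain + truth_w$loss
  attr(out, "truth") <- list(
    loh = spec$loh, tai = spec$tai, lst = spec$lst,
    gain = spec$gain, loss = spec$loss,
    pgc_nexus = 100 * cna_w / hl,
    pgc_freec = 100 * (cna_w + truth_w$tai + truth_w$loh) / hl)
  out
}

#' Simulate a differential-expression table with planted enriched sets
#'
#' Planted-set genes receive log-fold-changes centered at `effect` and small
#' p-values drawn from Beta(1 / (1 + effect), 1), both monotone in `effect`;
#' at `effect = 0` the planted genes are indistinguishable from the
#' null-distributed background. Random background gene sets are generated
#' alongside so enrichment has a family to control errors over.
#'
#' @param n_genes universe size.
#' @param planted_sets named list: either character vectors of member genes
#'   (must be subsets of the generated universe `g00001 ... gN`) or single
#'   numbers giving set sizes to sample.
#' @param effect planted effect strength (>= 0; 0 means no signal).
#' @param seed integer seed.
#' @param n_background_sets random unplanted sets to add to the collection.
#' @param background_size size range of background sets.
#' @return list with `de_table` (tibble `gene`, `log2fc`, `p_value`, `fdr`),
#'   `gene_sets` (named list) and `planted` (names of planted sets).
#' @export
simulate_de_table <- function(n_genes, planted_sets = list(), effect = 1,
                              seed = 1, n_background_sets = 10,
                              background_size = c(15, 60)) {
  if (n_genes < 1) abort("empty gene universe")
  if (effect < 0) abort("effect must be >= 0")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  sets <- lapply(planted_sets, function(s) {
    if (is.numeric(s) && length(s) == 1) {
      sample(genes, s)
    } else {
      bad <- setdiff(s, genes)
      if (length(bad) > 0) {
        abort(paste0("planted genes outside universe: ", paste(head(bad, 3), collapse = ", ")))
      }
      as.character(s)
    }
  })
  planted_genes <- unique(unlist(sets))

  log2fc <- rnorm(n_genes, 0, 1)
  p <- runif(n_genes)
  idx <- match(planted_genes, genes)
  if (length(idx) > 0) {
    p[idx] <- rbeta(length(idx), 1 / (1 + effect), 1)
    log2fc[idx] <- rnorm(length(idx), effect, 0.5)
  }
  de <- tibble(gene = genes, log2fc = log2fc, p_value = pmin(pmax(p, 1e-12), 1),
               fdr = p.adjust(pmin(pmax(p, 1e-12), 1), method = "BH"))

  bg <- list()
  if (n_background_sets > 0) {
    for (i in seq_len(n_background_sets)) {
      size <- sample(seq(background_size[1], background_size[2]), 1)
      bg[[sprintf("BACKGROUND_%02d", i)]] <- sample(genes, size)
    }
  }
  list(de_table = de, gene_sets = c(sets, bg), planted = names(sets))
}
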