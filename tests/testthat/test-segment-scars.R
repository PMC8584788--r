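# Scar scoring: counting rules, thresholds, PGC variants, labeling.

ref <- grch37_reference()

test_that("generic and FREEC segment dialects parse and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample = "s1", chrom = c("chr1", "chr1", "chr2"),
    start = c(1, 5e6, 1), end = c(4e6, 9e6, 2e6),
    cn = c(2, 3, 1), cn_state = c("neutral", "gain", "loss"),
    allelic_state = c("balanced", "unknown", "LOH")), path)
  tab <- read_segments(path, "generic", ref = ref)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cn_state, c("neutral", "gain", "loss"))

  # header-only file: empty table with a warning
  writeLines("sample\tchrom\tstart\tend", path)
  expect_warning(empty <- read_segments(path, "generic"), "no data rows")
  expect_equal(nrow(empty), 0)

  # end < start flags the offending record
  readr::write_tsv(tibble::tibble(sample = "s1", chrom = "chr1",
                                  start = 10, end = 5), path)
  expect_error(read_segments(path, "generic"), "row 1.*end.*start")

  # FREEC dialect maps its status column to cn_state
  readr::write_tsv(tibble::tibble(chrom = "chr3", start = c(1, 2e7),
                                  end = c(1e7, 5e7), copy_number = c(3, 2),
                                  status = c("gain", "normal")), path)
  freec <- read_segments(path, "freec_cnv", ref = ref, sample_id = "t1")
  expect_equal(freec$cn_state, c("gain", "neutral"))
  expect_equal(unique(freec$sample_id), "t1")

  # unknown chromosome is named in the error
  readr::write_tsv(tibble::tibble(sample = "s1", chrom = "chr99",
                                  start = 1, end = 10), path)
  expect_error(read_segments(path, "generic", ref = ref), "chr99")
})

test_that("hrd_loh counts long LOH, strictly over 15 Mb, autosomes only", {
  expect_equal(hrd_loh(seg("chr1", 1e6, 17e6 - 1, allelic_state = "LOH"), ref), 1)
  expect_equal(hrd_loh(seg("chr1", 1e6, 16e6 - 1, allelic_state = "LOH"), ref), 0)  # exactly 15 Mb
  expect_equal(hrd_loh(seg("chrX", 1e6, 30e6, allelic_state = "LOH"), ref), 0)
  expect_equal(hrd_loh(segs(), ref), 0)
})

test_that("whole-chromosome LOH is excluded unless the flag is lifted", {
  whole <- seg("chr21", 1, 48129895, allelic_state = "LOH")
  expect_equal(hrd_loh(whole, ref), 0)
  expect_equal(hrd_loh(whole, ref, exclude_whole_chromosome = FALSE), 1)
})

test_that("hrd_tai requires length, a telomeric boundary and no centromere overlap", {
  chr1_len <- 249250621
  telo <- seg("chr1", chr1_len - 12e6 + 1, chr1_len, allelic_state = "AI")
  expect_equal(hrd_tai(telo, ref), 1)
  interstitial <- seg("chr1", 150e6, 162e6 - 1, allelic_state = "AI")
  expect_equal(hrd_tai(interstitial, ref), 0)
  # touches the p terminus but crosses the chr13 centromere (16-19 Mb)
  crossing <- seg("chr13", 1, 17e6, allelic_state = "AI")
  expect_equal(hrd_tai(crossing, ref), 0)
  # tolerance admits near-telomeric boundaries
  near <- seg("chr1", chr1_len - 12e6, chr1_len - 1000, allelic_state = "AI")
  expect_equal(hrd_tai(near, ref), 0)
  expect_equal(hrd_tai(near, ref, terminus_tolerance = 1000), 1)
})

test_that("hrd_lst counts transitions between long regions across short gaps", {
  # adjacent 12 Mb cn2 and 11 Mb cn3 on one arm
  pair <- segs(seg("chr2", 1e6, 13e6 - 1, cn = 2),
               seg("chr2", 13e6, 24e6 - 1, cn = 3, cn_state = "gain"))
  expect_equal(hrd_lst(pair, ref), 1)

  # a 2 Mb interloper is filtered out; flanks still differ
  triple <- segs(seg("chr2", 1e6, 13e6 - 1, cn = 2),
                 seg("chr2", 13e6, 15e6 - 1, cn = 1, cn_state = "loss"),
                 seg("chr2", 15e6, 26e6 - 1, cn = 3, cn_state = "gain"))
  expect_equal(hrd_lst(triple, ref), 1)

  # both flanks below 10 Mb: no transition
  short_pair <- segs(seg("chr2", 1e6, 6e6 - 1, cn = 2),
                     seg("chr2", 6e6, 11e6 - 1, cn = 3, cn_state = "gain"))
  expect_equal(hrd_lst(short_pair, ref), 0)

  # identical state merges across a filtered gap instead of transitioning
  same_state <- segs(seg("chr2", 1e6, 13e6 - 1, cn = 2),
                     seg("chr2", 15e6, 27e6 - 1, cn = 2))
  expect_equal(hrd_lst(same_state, ref), 0)

  expect_error(hrd_lst(segs(seg("chr2", 1e6, 13e6), seg("chr2", 12e6, 25e6)), ref),
               "overlapping")
})

test_that("per-arm LST splits centromere-crossing segments, per-chromosome keeps them", {
  # chr2 centromere: 92326171-95326171. The left segment crosses it; per arm
  # its q-side remnant is only 5 Mb, below the 10 Mb flank requirement.
  cen_end <- 95326171
  straddle <- segs(seg("chr2", 92326171 - 15e6, cen_end + 5e6, cn = 2),
                   seg("chr2", cen_end + 5e6 + 1, cen_end + 5e6 + 15e6,
                       cn = 3, cn_state = "gain"))
  expect_equal(hrd_lst(straddle, ref, per_arm = TRUE), 0)
  expect_equal(hrd_lst(straddle, ref, per_arm = FALSE), 1)
})

test_that("pgc_nexus keeps >= 10 Mb gains and losses and ignores allelic calls", {
  expect_equal(pgc_nexus(segs(), ref), 0)
  g <- GRCH37_HAPLOID_LENGTH
  two <- segs(seg("chr1", 1e6, 1e6 + 20e6 - 1, cn = 3, cn_state = "gain"),
              seg("chr2", 1e6, 1e6 + 15e6 - 1, cn = 1, cn_state = "loss"))
  expect_equal(pgc_nexus(two, ref), 100 * 35e6 / g)
  # below 10 Mb filtered; exactly 10 Mb kept
  expect_equal(pgc_nexus(seg("chr1", 1, 10e6 - 1, cn = 3, cn_state = "gain"), ref), 0)
  expect_equal(pgc_nexus(seg("chr1", 1, 10e6, cn = 3, cn_state = "gain"), ref),
               100 * 10e6 / g)
  # allelic calls and sex chromosomes do not contribute
  expect_equal(pgc_nexus(seg("chr1", 1e6, 30e6, allelic_state = "LOH"), ref), 0)
  expect_equal(pgc_nexus(segs(seg("chrX", 1e6, 40e6, cn = 3, cn_state = "gain"),
                              seg("chrY", 1e6, 20e6, cn = 1, cn_state = "loss")),
                         ref), 0)
})

test_that("pgc_freec sums qualifying CNA, TAI and LOH widths as emitted", {
  g <- GRCH37_HAPLOID_LENGTH
  expect_equal(pgc_freec(segs(), ref), 0)
  chr1_len <- 249250621
  both <- segs(seg("chr1", 140e6, 140e6 + 16e6 - 1, allelic_state = "LOH"),
               seg("chr1", chr1_len - 12e6 + 1, chr1_len, allelic_state = "AI"))
  expect_equal(pgc_freec(both, ref), 100 * (16e6 + 12e6) / g)
  # the same interval called as CNA and LOH is counted twice (summed widths)
  double <- seg("chr1", 140e6, 140e6 + 16e6 - 1, cn = 1, cn_state = "loss",
                allelic_state = "LOH")
  expect_equal(pgc_freec(double, ref), 100 * 2 * 16e6 / g)
})

test_that("labels follow each scheme's published cutoff and comparison", {
  expect_equal(as.character(label_brcaness(42, threshold_scheme("HRD"))), "positive")
  expect_equal(as.character(label_brcaness(41.9, threshold_scheme("HRD"))), "negative")
  expect_equal(as.character(label_brcaness(32.0, threshold_scheme("PGC_NEXUS"))), "negative")
  expect_equal(as.character(label_brcaness(32.1, threshold_scheme("PGC_NEXUS"))), "positive")
  expect_equal(as.character(label_brcaness(28.5, threshold_scheme("PGC_FREEC"))), "positive")
  expect_error(threshold_scheme("WRONG"))
  # comparison is configurable (strict-> rule on the HRD scale)
  strict <- threshold_scheme("HRD", comparison = ">")
  expect_equal(as.character(label_brcaness(42, strict)), "negative")
})

test_that("scar_scores is additive and invariant to sex-chromosome content", {
  spec <- scar_spec(loh = 2, tai = 1, lst = 3, gain = 1, seed = 42)
  genome <- simulate_segments(spec)
  sc <- suppressMessages(scar_scores(genome, ref))
  expect_equal(sc$hrd_sum, sc$loh_count + sc$tai_count + sc$lst_count)
  expect_equal(sc$loh_count, 2)

  # piling events onto chrX/chrY changes nothing
  extra <- segs(seg("chrX", 1e6, 40e6, cn = 3, cn_state = "gain", sample_id = "synthetic_01"),
                seg("chrY", 1, 20e6, allelic_state = "LOH", sample_id = "synthetic_01"))
  sc2 <- suppressMessages(scar_scores(dplyr::bind_rows(genome, extra), ref))
  expect_equal(sc2[, names(sc)], sc)
})

test_that("splitting a segment into identical-state halves leaves LST and PGC unchanged", {
  base <- segs(seg("chr4", 1e6, 25e6, cn = 2),
               seg("chr4", 25e6 + 1, 45e6, cn = 3, cn_state = "gain"))
  split <- segs(seg("chr4", 1e6, 12e6, cn = 2),
                seg("chr4", 12e6 + 1, 25e6, cn = 2),
                seg("chr4", 25e6 + 1, 35e6, cn = 3, cn_state = "gain"),
                seg("chr4", 35e6 + 1, 45e6, cn = 3, cn_state = "gain"))
  expect_equal(hrd_lst(split, ref), hrd_lst(base, ref))
  expect_equal(pgc_nexus(split, ref), pgc_nexus(base, ref))
  expect_equal(pgc_freec(split, ref), pgc_freec(base, ref))
})

test_that("appending a disjoint qualifying gain never decreases pgc_nexus", {
  genome <- random_genome(7)
  before <- pgc_nexus(genome, ref)
  bigger <- dplyr::bind_rows(genome, seg("chr22", 20e6, 35e6, cn = 3, cn_state = "gain"))
  expect_gte(pgc_nexus(bigger, ref), before)
})

test_that("all scores match the brute-force oracle on random genomes", {
  for (s in 1:25) expect_scores_match_oracle(random_genome(s))
})

test_that("calibrate_threshold finds the concordance-maximizing midpoint", {
  expect_equal(calibrate_threshold(c(1, 2, 3, 10, 11),
                                   c("negative", "negative", "negative",
                                     "positive", "positive")), 6.5)
  expect_warning(
    c0 <- calibrate_threshold(rep(5, 4), c("negative", "negative", "positive", "positive")),
    "identical")
  expect_true(is.finite(c0))
  expect_error(calibrate_threshold(1:3, rep("positive", 3)), "single class")

  set.seed(11)
  for (i in 1:20) {
    scores <- round(runif(12, 0, 10), 1)
    labels <- sample(c("negative", "positive"), 12, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(calibrate_threshold(scores, labels), oracle_calibrate(scores, labels))
  }
})
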