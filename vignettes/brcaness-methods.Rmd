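---
title: "Methods: genomic-scar scoring, delta-variance selection, and the BRCAness classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic-scar scoring, delta-variance selection, and the BRCAness classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brcaness)
```

This vignette explains the statistical machinery in `brcaness`, the
assumptions behind each stage, and the design choices made where the
underlying methods admit more than one defensible reading.

## The scoring model

Homologous-recombination-deficient (HRD) tumors accumulate characteristic
large-scale rearrangements ("genomic scars"). Three scar counts are summed
into the HRD score, with a sample called BRCAness-positive at HRD ≥ 42:

* **HRD-LOH** counts loss-of-heterozygosity segments *strictly* longer than
  15 Mb on autosomes. Whole-chromosome LOH (a segment covering base 1 to the
  chromosome end) is excluded by default — it usually reflects aneuploidy
  rather than recombination failure — and the exclusion is flag-controlled
  because the counting rule itself does not force it.
* **HRD-TAI** counts allelic-imbalance segments strictly longer than 11 Mb
  whose boundary reaches a chromosome terminus (within a configurable
  tolerance, default 0 bp) and which do not overlap the centromere interval.
  LOH segments are *not* counted as TAI even when subtelomeric; the two
  allelic states are kept distinct.
* **HRD-LST** counts breakpoints between adjacent copy-number regions after
  a smoothing step: segments shorter than 3 Mb are discarded, neighbouring
  segments of identical copy-number state within a 3 Mb gap are merged, and
  a breakpoint is counted when two merged regions of at least 10 Mb each,
  differing in state, lie within 3 Mb of each other. The 3 Mb adjacency
  allowance comes from the original large-scale-transition definition; a
  literal "any adjacency" reading is not computable on genomes with
  unsegmented space and would count transitions across arbitrarily large
  gaps. LST is computed per chromosome arm by default (segments straddling
  the centromere are split at it), switchable to per-chromosome. The
  ploidy-adjusted LST positivity cutoff used by some assays is not
  implemented — no formula is available — and a note is emitted whenever LST
  is reported.

Two **percent-of-genome-changed** (PGC) surrogates approximate HRD from
copy-number callers that do not emit all three scar types. `pgc_nexus` sums
widths of autosomal gains and losses of at least 10 Mb ("remove gains/losses
smaller than 10,000 kb" keeps exactly the ≥ 10 Mb ones) over the GRCh37
haploid genome length (3,234,834,689 bp), as a percent; allelic calls are
ignored. `pgc_freec` additionally sums qualifying TAI and LOH widths. Widths
are summed *as emitted*: an interval called both as a CNA and as LOH counts
twice, so the value can exceed 100 on pathological input — this is the
documented "summed width" behavior, not a bug. Whether overlapping calls
should be merged first is unknowable from the published description; the
non-merging reading is simpler and exactly reproducible.

Published cutoffs: HRD ≥ 42 (the boundary is ambiguous between "above 42"
and "≥ 42" in the source material; we adopt ≥ 42, the form used by the
original threshold-derivation study, and make the comparison configurable),
PGC-NexusCN > 32, PGC-FREEC > 28 (both strict, "above"). Coordinates are
1-based inclusive throughout and width = end − start + 1, matching SEG-file
conventions. `calibrate_threshold()` transfers a labeling onto a new score
scale by exhaustive concordance maximization over the midpoints between
consecutive distinct scores, returning the smallest maximizing cutoff.

## Delta-variance feature selection

For probes × samples beta values in [0, 1] with binary labels, the per-probe
statistic is Δ = var_all − (var_pos + var_neg), with all variances using the
n − 1 denominator (changing the denominator shifts every Δ systematically).
Δ > 0 requires the between-class mean separation — which inflates var_all
but neither within-class variance — to exceed the *sum* of the within-class
variances. This is a deliberately conservative filter: on noisy tumor
cohorts only a fraction of a percent of probes pass, and under label
permutation essentially none do, which is exactly what makes the count of
positive-Δ probes a usable test statistic for class structure.

Design choices:

* **Ranking and ties.** Probes are ranked by decreasing Δ, ties broken
  lexicographically by probe id, making the top-k cut deterministic.
* **Decorrelation.** Greedy in rank order: a probe is kept iff its absolute
  correlation with every already-kept probe is ≤ 0.8; the rank-1 probe is
  always kept. The greedy order favors informative probes, and the procedure
  is deterministic. Spearman is the default (the 0.8 screen is quoted as a
  ρ threshold, suggesting ranks); Pearson is available. Zero-variance probes
  have undefined correlation and are dropped with a warning rather than
  failing the run.
* **Permutation null.** Labels are shuffled preserving class sizes (not
  resampled), 1000 times by default, and the positive-Δ count recorded. The
  empirical p uses the (1 + exceedances)/(n_perm + 1) correction so p = 0 is
  unattainable. All permutation draws derive from an explicit seed and are
  bit-reproducible.
* **Missing values.** Probes with any missing beta are dropped (with a
  count message) before variance computation: group variances of
  incomplete rows are not comparable across groups. Upstream array
  pipelines normally guarantee completeness.
* **Sample-exclusion scan.** Leave-one-out recomputation of the positive-Δ
  count identifies samples that blur the class structure (mislabeled or
  borderline tumors); the sample whose removal maximizes the count is the
  first exclusion candidate.
* **Shadow features.** Each candidate probe is paired with a row-permuted
  copy of itself; over n_rep forest fits, a probe's empirical p is the
  corrected fraction of repetitions in which its Gini importance failed to
  beat the best shadow. This is the standard shadow-feature scheme; the
  "modified" variant it stands in for is unspecified in the source
  material, so the standard construction is implemented and documented as
  such.

## The classifier and its evaluation

The forest uses 10,000 trees, 32 candidate variables per node (well above
√p on purpose, following the published configuration; capped at the feature
count when fewer probes are retained), minimum node size 3, and no depth
limit. Class imbalance is handled by per-tree stratified bootstrapping:
each tree draws min-class-size samples *with replacement* from each class.
The published description says only "stratified for class balancing"; the
per-tree balanced bootstrap is the standard reading in the randomForest
implementation and is switchable off.

A sample's **vote fraction** is the share of trees voting positive;
positivity requires strictly more than half the votes, so a 0.5 tie stays
negative. Accuracy metrics are (TP+TN)/total, TP/(TP+FN) and TN/(TN+FP) in
percent, rounded to integers only for reporting.

**Nested cross-validation.** Feature selection inside the fold loop is the
load-bearing detail: Δ-ranking, the top-2000 cut and decorrelation are
recomputed from the training samples of each fold only, so the held-out
fold never influences which probes the fold model sees. Selecting features
once on the full data and then cross-validating would leak information and
overstate accuracy. Folds are stratified, shuffled once under the run seed,
with remainder samples assigned to the earliest folds. Fold confusion
matrices are pooled elementwise; the **combined AUC** is computed from the
pooled held-out votes as one ROC (not as a mean of fold AUCs), by trapezoid
integration — equivalent to the Mann–Whitney statistic with ties counted
one half. Fold models are discarded; the deployable model is retrained on
all samples.

## Preranked enrichment

Genes are ranked by sign(log2FC) × 1/p with p floored at 1e-300 to keep the
metric finite; ties break by gene id. The classic (unweighted) enrichment
score steps +1/N_h at set members and −1/(N−N_h) elsewhere; the ES is the
signed maximal deviation of the running sum, in [−1, 1], with the first
occurrence winning when the positive and negative extremes tie in
magnitude. The "no normalization" mode (NES = ES) matches reports whose NES
magnitudes equal their ES. In such reports the negative-score section may
print |ES| with a signed NES; this implementation always reports signed ES.

Because the input is a preranked list, sample permutation is impossible;
the null permutes gene labels of the ranked list, one shared permutation
per iteration across all sets so the family-wise maximum statistic is
coherent. Nominal p counts same-sign exceedances with the +1 correction
over n_perm + 1 — under the null this statistic is uniform-like on
(0, 1/2], since only the same-sign half of permutations can qualify. FWER
uses the per-permutation max of same-sign |ES| over all sets, computed
separately for the positive- and negative-score families (mirroring the
two-section report structure), also with the +1 correction; the plain
fraction could otherwise fall below the nominal p it is supposed to
dominate. FDR columns are Benjamini–Hochberg over nominal p within each
family — an honest summary, not a replication of the reference
implementation's q-value. Size filters default to the conventional 15–500
after intersection with the ranked universe.

## What the synthetic generators emulate

`simulate_cohort()` draws beta values from Beta(μc, (1−μ)c)
distributions — the (mean, concentration) parameterization keeps support in
[0, 1] and decouples spread from location. Background probes are
exchangeable between classes (probe means uniform on 0.15–0.85,
concentration 100). Informative probes copy the observed real-data pattern:
the positive class is *hypomethylated* (mean shift −0.3 from a 0.6
baseline) with *inflated spread* (concentration halved). The shift and
concentration were chosen once so that the planted probes sit in the regime
the method assumes — the between-class term p(1−p)·shift² ≈ 0.022 exceeds
the summed within-class variances ≈ 0.007, giving positive expected Δ — and
are documented here as fixture parameters, not as biology: no quantitative
methylation effect sizes are available to copy. Class sizes default to
26/17, the labeled-cohort split of the motivating study. What the generator
deliberately omits: batch effects, probe-type chemistry differences,
beta-value compression near 0/1, and probe–probe correlation structure.
Passing tests therefore demonstrate correctness of the *algorithms* under
the assumed signal model, not expected performance on real arrays.

`simulate_segments()` places requested qualifying events (LOH > 15 Mb,
TAI > 11 Mb telomeric, LST pairs of ≥ 10 Mb flanks optionally separated by
a sub-3 Mb spacer, CNAs ≥ 10 Mb) on chromosome arms with > 3 Mb buffers
between events, then completes every chromosome with sub-3 Mb neutral
filler. Two consequences are bookkept rather than avoided: the gain flank
of every LST pair necessarily qualifies for both PGC variants, and planted
TAI/LOH events contribute to the FREEC PGC; the generator records exact
expected counts *and* PGC percents at placement time in a `truth`
attribute, which is what parameter-recovery tests compare against.

`simulate_de_table()` gives planted genes Beta(1/(1+effect), 1) p-values
and log-fold-changes centered at `effect`; at effect = 0 planted genes are
exactly null (both sign and p), which is what makes the null-calibration
check meaningful.

## Numerical choices

* Row variances are computed from centered residuals (two-pass), not the
  one-pass sum-of-squares identity, so near-constant probes do not lose
  precision to cancellation; agreement with an explicit two-pass oracle is
  at 1e-12 relative.
* The enrichment score is evaluated sparsely from integer hit/miss counts
  at candidate extrema (just before and at each hit), which is algebraically
  and bitwise identical to a full running-sum scan with the same
  first-occurrence tie-break.
* ROC curves collapse tied vote values into single points before trapezoid
  integration, which is what makes the AUC equal the pair-counting
  statistic under ties.
* Every stochastic entry point takes an explicit integer seed; internal
  stages derive independent sub-seeds from it, so whole pipelines are
  bit-reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: 200 random segment
genomes against a brute-force enumerator; planted scar-count grids up to
{0..5}³; 40-sample × 5000-probe cohorts with 0 or 100 informative probes
and 1000-permutation nulls; nested 5-fold cross-validation with the
top-2000/ρ ≤ 0.8 selection chain and 500-tree fold models; and
2000-gene enrichment with 1000 permutations. These sizes were chosen as the
smallest at which each statistical property is unambiguous; the tree count
is reduced from the production default of 10,000 because vote fractions
stabilize well below that for cohorts of this size.

## Known limitations

* The scar scores consume segment calls; they cannot compensate for poor
  upstream segmentation, purity or ploidy estimation, and no
  ploidy-adjusted LST cutoff is applied.
* PGC thresholds (32/28) were matched to the HRD ≥ 42 scale on a specific
  tumor cohort; transferring them to other entities should go through
  `calibrate_threshold()` on jointly scored samples.
* The classifier's labels inherit whatever the scar-based threshold got
  wrong; its accuracy is bounded by the labeling method.
* `harmonize_beta()` intersects probe sets only; it assumes the matrices
  were normalized together and performs no cross-platform rescaling.
* The enrichment null permutes gene labels, which ignores gene–gene
  correlation; FWER control is with respect to that null, as in any
  preranked analysis.
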