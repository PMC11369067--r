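---
title: "Quantifying donor engraftment after FMT: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying donor engraftment after FMT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engraftkit)
```

## The problem

After faecal microbiota transplantation (FMT), how much of the donor's
microbiota actually establishes itself in the recipient? `engraftkit`
quantifies engraftment from longitudinal species-level relative-abundance
profiles of donors and recipients, as collected in randomized FMT trials for
ulcerative colitis (UC): two well-characterised donors sampled repeatedly
over the trial, and recipients sampled before FMT (baseline and after
pretreatment/bowel lavage) and repeatedly after a series of weekly FMT
infusions. The same framework applies to any FMT cohort with donor,
pre-FMT, and post-FMT profiles.

Everything downstream operates on *relative* abundances with a detection
limit `tau` (default 0.001, i.e. 0.1%): a species is "present" in a sample
iff its relative abundance is at least `tau`. Sub-threshold mass is
discarded rather than redistributed — the retained fraction per sample is
reported so the analyst can see how much signal the threshold removes
(typically a few percent). A `renormalize` flag re-closes rows for
sensitivity analyses.

## From donor profiles to a tracking universe

**Donor core species.** A donor's core microbiome is the set of species
present (>= `tau`) in at least `min_samples` of that donor's longitudinal
samples (default 6, an absolute count chosen for donors with 13-14 samples,
i.e. roughly 45% prevalence; a fractional cutoff is available for cohorts
with different sampling depth). Prevalence filtering removes transient and
borderline taxa so that only species consistently delivered by the
transplanted material are tracked.

**Putatively donor-derived species.** For each recipient, core species
detected in *any* pre-FMT sample are excluded: a species the patient
already carried cannot be claimed as engrafted. We use the union of all
pre-FMT samples (weeks 0 and 3 in the default layout) as the baseline
because it is the conservative exclusion — one detection anywhere before
FMT disqualifies the species. The remainder is the donor-derived set
`DD(r)`, the universe within which engraftment is scored for recipient `r`.

## The three engraftment metrics

For recipient `r` with post-FMT samples `t` in a window `W`:

1. **Species Engraftment Index (SEI)** — per sample, the summed relative
   abundance of detected donor-derived species; per window, the median over
   the window's samples. SEI in [0, 1] measures the *displacement* of the
   recipient microbiome by donor-derived taxa.
2. **Species Engraftment Fraction (SEF)** — the fraction of `DD(r)`
   detected in at least one sample of the window. SEF in [0, 1] measures
   the *diversity* of donor species introduced, regardless of abundance.
   A recipient with an empty donor-derived set has no defined SEF and is
   flagged and excluded from SEF comparisons.
3. **Aitchison similarity to donor** — compositions are compared with the
   Aitchison distance (Euclidean distance between centred log-ratio
   transforms). For each window sample the median distance to all of the
   assigned donor's samples is computed; the window distance is the median
   of those per-timepoint values; similarity is
   `baseline distance / window distance`, where the baseline is the
   recipient's week-3 sample (after pretreatment and lavage, before the
   first infusion). Similarity > 1 means the recipient moved toward the
   donor. This is the reciprocal of the baseline-normalised distance, a
   single monotone "high = more engraftment" quantity; the alternative
   reading (pool all pairwise distances in the window, then one median) is
   available via `pool_pairwise = TRUE` and differs little in practice.

**Windows.** The acute window (weeks 4-7) covers the samples taken one week
after each of the four weekly infusions; the durable window (weeks 8-14)
the samples from two weeks after the last infusion onwards; overall spans
weeks 4-14. Subjects contribute to the windows in which they have samples;
dropouts are not imputed. All medians use the base-R convention (even
lengths average the two central order statistics).

**Total engraftment score.** The three metrics live on different scales, so
per window the cohort median SEF is taken as the reference, SEI and
similarity are rescaled to have exactly that median across subjects, and
the total is the sum `sef + scale_sei * sei + scale_sim * similarity`. The
scales are recorded per window so the equal-median construction can be
verified (it holds to machine precision by construction) and results
reproduced. Per-window scales were chosen over one global scale because the
three windows have systematically different similarity levels; rankings
within a window are unaffected by any positive rescaling of a single
metric. If a metric's cohort median is zero its scale is set to zero (its
contribution is dropped) with a warning.

## Compositional details

The centred log-ratio transform requires strictly positive entries. Zeros
(true absences and thresholded values alike) are replaced multiplicatively
with a pseudocount of `tau/2` (default 5e-4) and the vector is re-closed
before taking logs. Tying the pseudocount to the detection limit makes the
imputed value "half the smallest abundance that counts as present", the
usual convention for detection-limited data. Distances between two samples
are computed on the union of species detected in either sample; the zeros
introduced by union-filling receive the pseudocount. For distance matrices
over many samples (PERMANOVA, ordination) the universe is the union over
all samples. The transform errors on all-zero vectors, and similarity is
undefined (an error) if a recipient's baseline is compositionally identical
to the donor.

## Clinical response rules

Disease activity is graded by the Mayo score: three clinical subscores
(stool frequency, rectal bleeding, physician global assessment; each 0-3,
summing to the partial Mayo, 0-9) plus an endoscopic subscore on the
ordered scale 0 < 1a < 1b < 2 < 3, where grade 1 is split into 1a (erythema
without friability) and 1b (with friability). Both 1a and 1b contribute the
numeric value 1 to the full Mayo sum, but a change from 1b to 1a counts as
a one-step endoscopic improvement.

* **Week 10** (partial Mayo only): remission iff partial Mayo <= 2 with no
  individual clinical subscore above 2; partial response iff the partial
  Mayo decreased by >= 3 points from baseline; otherwise no response.
* **Week 14** (full Mayo): remission additionally requires an endoscopic
  score of 0 or 1a; partial remission requires the >= 3-point clinical
  decrease *and* at least one step down the endoscopic scale.
* Dropout due to progressive disease is a treatment failure (no response)
  at both weeks. Responders pool remission and partial remission.

The "no individual sub score above 2" cap is implemented literally even
though it is nearly redundant given partial Mayo <= 2; a
`remission_subscore_max` argument lets users apply the stricter
conventional cap of 1. The classifier is deterministic and total, and is
tested exhaustively against an independent restatement of the rules.

## Statistics

Standard engines are used behind the package's interfaces: Fisher's exact
test (two-sided by the point-probability rule — the sum of all tables with
the observed margins no more probable than the observed one — which is the
convention that reproduces the trial's printed contingency p-values;
`stats::fisher.test` implements exactly this rule), the Pearson chi-square
with optional Yates correction, the Wilcoxon rank-sum test (exact
enumeration when both groups have <= 12 untied observations, mid-rank
normal approximation with tie correction otherwise), two-way ANOVA with
Type II sums of squares on the additive model (each factor's effect
controlling for the other — appropriate for the unbalanced designs left by
dropouts; `car::Anova`), PERMANOVA via `vegan::adonis2` (pseudo-F with
p = (1 + #{permuted F >= observed}) / (1 + n_perm), default 999
permutations, Aitchison distances by default for consistency with the
engraftment metrics), observed richness and Shannon diversity
(natural-log, on detected taxa re-closed to unit sum), and complete-linkage
hierarchical clustering of donors on Euclidean distances between mean
family-level profiles.

## What the synthetic cohort emulates

Real FMT trial metagenomes are rarely public, so the package ships a
generator that reproduces the *structure* of such a trial with known ground
truth. Defaults are fixed to the target layout: 2 donors with 13 and 14
samples, 24 recipients, pre-FMT samples at weeks 0 and 3, post-FMT samples
at weeks 4, 5, 6, 7, 8, 10, 14, a 500-species pool, 250/180 species per
donor, 120-species recipient baselines sharing 40% of the donor pool, and
recipients alternating between donors with pretreatment arms crossed over
donors in blocks.

* **Abundances** are log-normal base compositions (heavy-tailed, so donors
  carry a realistic fraction of sub-detection species) resampled per sample
  Dirichlet-style with one dispersion knob (default 300), plus independent
  per-species dropout (default 5%) so detection prevalence varies and the
  core-species rule has something to filter. Every generated row closes to
  unit sum before thresholding.
* **Engraftment forward model**: each post-FMT sample at week `w` is a
  noisy draw from the re-closed convex mixture
  `(1 - lambda_w) * baseline + lambda_w * donor base`. The per-recipient
  mixing fraction `lambda` is the ground-truth engraftment intensity;
  by default recipients are spread evenly over 0.05-0.70 (constant over
  weeks) so the cohort spans weak to strong engraftment for
  parameter-recovery checks.
* **Detectability floor**: recipient baseline species are seeded at >= 0.5%
  abundance. A species counted as "present before FMT" must be reliably
  detectable — otherwise "presence" is ill-defined relative to the
  detection limit, and species flickering around `tau` leak through the
  pre-FMT exclusion and register as false engraftment. With the floor, the
  false-engraftment noise floor under `lambda = 0` is ~1% mean SEF. Donor
  profiles keep their full heavy tail.
* **Ground truth**: the true engrafted set per recipient is the donor's
  species at >= 0.1% in its base composition minus the recipient's baseline
  species — species transferred below the detection limit are untrackable
  in principle and are not counted. `lambda` per week is recorded.
* **Clinical generator**: constructive, not probabilistic — it works
  backwards from requested remission/partial/none counts (default: the
  trial-like 10/24 week-10 and week-14 responder structure with 80% of
  week-14 responders on the second donor) to Mayo component scores, then
  verifies by running the classifier; tests against it are exact.

The generator does *not* emulate phylogenetic correlation between species,
strain-level dynamics, time-autocorrelated noise, sequencing or
classification error, or covariation between clinical outcome and
microbiome composition (clinical outcomes are generated independently of
the profiles). Passing tests therefore demonstrate that the pipeline
recovers engraftment signal under a plausible compositional noise model —
not that it is robust to every failure mode of real metagenomic data.

## Problem sizes and numerical tolerances

The validation suite runs the full 24-recipient cohort for parameter
recovery (Spearman correlation between `lambda` and the total score,
observed ~0.97 at the default settings), exhaustive Fisher-vs-enumeration
sweeps over all 2x2 tables with total <= 30, full enumeration oracles for
the Wilcoxon exact p at group sizes <= 7, 1000 random composition triples
for the metric axioms, 500 null simulations (199 permutations each) for
PERMANOVA and ANOVA type-I-error calibration at alpha = 0.05, and the
complete clinical truth table. Equality of scaled medians is asserted to
1e-9; closed-form clr/Aitchison values to 1e-12; permutation p-values are
seed-reproducible bit-for-bit.

## Known limitations

Species identity is by exact name string — profiles must come from one
classifier's namespace. Strain-level tracking, which would distinguish a
donor strain from a conspecific recipient strain, is out of scope; a
species shared between donor core and recipient baseline is excluded from
the tracking universe even if the donor's strain in fact replaced the
recipient's. The SEF treats all donor-derived species equally regardless of
abundance, and the similarity metric depends on a single week-3 baseline
sample. Cohort-level score normalisation means a subject's total score is
not comparable across cohorts, only within one.
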