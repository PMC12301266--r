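---
title: "Metabolic signatures for IMD screening: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic signatures for IMD screening: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inherited metabolic disorders (IMDs) are individually rare, collectively
numerous, and biochemically diverse. A screening laboratory rarely holds more
than a handful of confirmed samples per disorder, new samples arrive slowly,
and metabolite coverage differs between platforms. `imdsig` implements a
diagnostic workflow built for exactly this regime: it learns a compact
*metabolic signature* per disorder from as little as one confirmed patient
sample, refines each signature as further samples arrive, and ranks candidate
disorders for an undiagnosed sample by matching its standardized metabolic
profile against the signature store.

```{r, eval = FALSE}
library(imdsig)
cohort <- make_case_study_fixture(1) # 136 controls, 77 patients, 35 IMDs
```

## Preprocessing model

**QC filtering.** Untargeted LC-MS features are retained only if they are
analytically reproducible across repeated pooled-QC injections:
retention-time CV strictly below 2%, mean mass deviation within ±5 ppm of
the theoretical m/z (inclusive), and peak-area CV strictly below 20%. CVs use
the n−1 standard deviation throughout the package. Features without a
reference mass skip the ppm criterion and are flagged rather than dropped;
zero-area peaks are rejected and flagged rather than crashing the run.

**Internal-standard normalization.** Within each acquisition method (e.g.
RP+, RP−, HILIC−), intensities are divided per sample by the spiked
stable-isotope internal standard with the lowest CV across pooled-QC
injections, then the standard itself is removed. Ties go to the first
candidate listed; a candidate unmeasured in any QC injection is ineligible.

**Limit-of-detection imputation.** Missing cells are treated as
below-detection measurements and imputed per feature. Instrument LODs are
not available downstream of raw data, so the default estimate is the
feature's minimum positive observed intensity; a half-minimum policy is
available. Fully unobserved features are dropped with a warning.

**Log transform.** The analysis entry points standardize log intensities
(`cv_scheme(log_intensities = TRUE)`, the default). LC-MS intensity noise is
multiplicative: on the raw scale, z-scores of log-normally distributed
intensities are strongly right-skewed, background z-values above 4 are
routine, and a single extreme background feature can dominate a similarity
score. On the log scale, control z-values are approximately standard normal
and a "k SD" marker effect means what it says. The z-scoring function itself
is transform-agnostic, so raw-scale analyses remain possible.

**Control-referenced z-scores.** Every profile is expressed as
`z = (x − mean_controls) / sd_controls` per feature, with the control set
depending on context (below). Features constant across the reference
controls are dropped with a warning by default; an epsilon-floor policy is
available, but infinite or near-infinite z-values would otherwise dominate
every downstream dissimilarity.

## Phase 1 — signature discovery

For a target patient sample, two kinds of small training sets are built:

* **set1** — the target plus five controls drawn from the control pool,
  z-referenced to those five controls. Three such replicates are drawn by
  default (`n_set1 = 3`): more replicates sharpen the intersection below but
  quickly empty it, because a six-sample set gives noisy weights.
* **set2** — the target plus one sample of a *different* disorder (or, in
  refinement, an existing signature's reference profile), z-referenced to
  the full control pool since the pair contains no controls of its own. One
  set2 per other disorder.

Each set is decomposed into per-feature dissimilarity contributions
(squared z-differences by default; absolute differences selectable) and fed
to the sparse hierarchical clustering weight problem:

maximize Σ<sub>pairs</sub> u<sub>pair</sub> Σ<sub>j</sub> w<sub>j</sub>
D[pair, j] subject to ‖u‖₂ ≤ 1, ‖w‖₂ ≤ 1, ‖w‖₁ ≤ s, w ≥ 0.

The weight w<sub>j</sub> measures metabolite j's contribution to separating
the samples; the L1 bound `s` (default `sqrt(p)/2`, range `[1, sqrt(p)]`)
controls sparsity. The solver alternates the closed-form u-update with a
soft-thresholded w-update whose threshold is found by bisection so the L1
constraint binds. Because the objective is convex in `w`, alternating ascent
can stall on a suboptimal support; the solver therefore runs three
deterministic starts (uniform, column-norm direction, best single column)
and keeps the best stationary point. Determinism was preferred over random
restarts so that a signature store is exactly reproducible from its inputs.
A permutation-based gap-statistic tuner for `s` is provided
(`tune_l1_bound()`) but is not the default: with six-sample training sets
its selection is unstable.

The signature's metabolites are the **intersection** of the top-20 weighted
metabolites across the set1 replicates, **unioned** with the single
top-weighted metabolite from every set2. Each metabolite's reference score
is the mean of the target sample's z-values across all training sets, so
scores are expressed in control-SD units. An empty selection (possible if
`n_set1` is large and `k_top` small) is an error suggesting the remedy, not
a silent empty signature.

## Phase 2 — refinement

A new patient sample of an already-covered disorder triggers a fresh
Phase-1 discovery (set2 companions can be the existing signatures of other
disorders, which avoids needing their raw samples), and the new signature is
merged into the old:

* metabolites present in both: running mean
  `(n·old + new) / (n + 1)`, with `n` the metabolite's accumulated
  contribution count — earlier rounds carry proportionally more weight, so
  an outlier sample cannot overturn an established score;
* metabolites absent from the incoming signature: the default `"decay"`
  policy records a zero observation, `n·old / (n + 1)`. Entries specific to
  a single training sample are thereby gradually phased out, while
  repeatedly confirmed markers are repeatedly reinforced. A `"keep"` policy
  that freezes such entries is available for comparison;
* newly appearing metabolites enter at their observed score with a count
  of 1, so they carry little cumulative weight until confirmed. For
  metabolites that enter the assay panel outside refinement,
  `seed_new_metabolite()` adds an entry damped by a configurable factor
  (default 0.1).

Under independent noisy rounds the reference score behaves as a running
mean: its variance decays as 1/n, which the test suite checks by
simulation.

Expert knowledge enters through `apply_expert_weights()`: per-metabolite
multiplicative factors applied at scoring time without altering learned
scores — e.g. down-weighting the metabolites shared by two biochemically
related disorders before a second-pass subtype comparison.

## Phase 3 — ranked diagnosis

An undiagnosed sample is analyzed alongside five control samples, its
profile z-referenced to them, and scored against every stored signature.
The score is a normalized dot product over the metabolites present in both
the sample's panel and the signature — unmeasured signature metabolites are
excluded from both vectors rather than zero-filled, so partial coverage
degrades the shared-metabolite count (which is reported) instead of the
score itself.

Two normalizations are provided. The default divides the dot product by the
**signature norm only**: the score is then the length of the sample's
projection onto the signature direction, in control-SD units, so a strong
and correctly oriented metabolic deviation scores high while a weak profile
that merely points the right way cannot. Full **cosine** normalization
(both norms, bounded in [−1, 1]) is selectable, but its invariance to the
sample's scale discards the magnitude of the deviation — with five-control
references, whose z-values have heavy t-like tails, weak chance-aligned
profiles then regularly outrank strong matched ones, which is why it is not
the default. Candidates are sorted descending, ties broken by disorder id
and flagged, no-coverage signatures ranked last and flagged; the top three
(rank 1–3) are highlighted as the probable diagnoses.

## Evaluation harness

`run_cross_validation()` implements repeated random sub-sampling: in each of
100 repetitions (default) samples are re-drawn within each class into
training controls (20), test controls (5), and per disorder with `m`
samples: one discovery sample, `min(3, m − 3)` refinement samples (one per
round), and the remaining `m − 1 − n_refine` as test samples. This
allocation reproduces the published evaluation topology for the
case-study-1 cohort: 46 patient + 20 control training samples, 31 test
samples from the 12 multi-sample disorders plus 5 test controls, and
refinement restricted to the four disorders with at least five samples.
Test samples are diagnosed after initial discovery and again after each
refinement round; the rank of the true disorder is recorded, and counts are
aggregated as mean (SD across repetitions) per stage and per disorder. Test
controls have no true disorder; their top similarity per stage is kept as a
false-positive summary. Singleton disorders contribute to discovery and to
set2 companions but are excluded from testing with a message.

## The synthetic cohort generator

No clinical data ship with the package; every stage is exercised on a
seeded generator that emulates the statistical structure the algorithm
assumes:

* per-feature log-normal baselines (location uniform on `log(1e4)`–`log(1e7)`,
  log-SD uniform on 0.2–0.6, typical of untargeted plasma panels);
* per-disorder marker sets (default 5 markers) shifted on the log scale by
  `effect × log-SD`, effects drawn uniformly from a configurable range, 80%
  of markers elevated and the rest depleted;
* optional marker sharing between designated disorder pairs, emulating
  biochemically related IMDs;
* treated patients with effects attenuated by a configurable factor
  (default 0.5);
* intensity-dependent missingness: values below the feature's
  `missing_rate` control quantile are censored, matching the
  limit-of-detection rationale for imputation;
* pooled-QC sample rows, one low-CV internal standard per acquisition
  method, and a per-feature peak-QC table in which a configurable fraction
  of non-marker features deliberately violates one retention criterion.

`make_case_study_fixture()` instantiates the two published cohort
topologies: fixture 1 with 136 controls and 77 patients across 35 IMDs
(multiplicities 17, 7, 7, 5, 3, 3, six 2s, and 23 singletons), fixture 2
with 68 controls and 95 patients across 11 IMDs. The fixture uses 500
features, marker effects of 5–8 control SDs, one disorder pair sharing two
of five markers, and roughly a quarter of multi-sample disorders' extra
samples marked treated; these sizes keep a full 100-repetition
cross-validation at desk scale while preserving the phenomena that matter
(near-duplicate signatures, attenuated test profiles, censoring).

What the generator does **not** emulate: retention-time drift and batch
effects, correlated metabolite blocks (pathway structure), age- and
sex-dependent reference variation, annotation ambiguity, and non-Gaussian
biological outliers. Passing tests on this cohort therefore demonstrate the
machinery — selection, weighting, refinement arithmetic, ranking, and their
statistical calibration — not clinical performance; the published
evaluation on real cohorts reports substantially lower rank-1 rates than
the clean synthetic ceiling, and nothing here contradicts that.

## Numerical choices and degenerate inputs

* CVs and SDs use the n−1 denominator everywhere; thresholds are strict
  (`<`) for the two CV criteria and inclusive (`≤`) for ppm, following the
  criteria's wording.
* The solver converges on `max |Δw| < 1e-6` with at most 100 iterations per
  start; bisection runs 60 halvings. Weight ties in top-k selection break
  lexicographically by feature id, making selections order-independent.
* Zero control SD: feature dropped (default) or epsilon-floored. Zero-mean
  QC peak area: feature rejected and flagged. All-zero dissimilarity: error.
* Signature stores are written canonically (sorted keys, full precision,
  unboxed scalars), so write–read–write round trips are byte-identical and
  runs are diffable.
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; the cross-validation harness derives all its
  draws from one master seed, so the full evaluation is bit-reproducible.

## Known limitations

* One signature per disorder id: subtypes must be modelled as separate ids
  or separated by expert re-weighting; no automatic merging of related
  disorders.
* Rank-1 discrimination is limited by the five-control z-reference: with
  only 4 degrees of freedom in the SD estimate, background z-values have
  heavy tails, which is the main driver of residual misranking and the main
  reason the magnitude-aware similarity normalization is the default.
* The discovery rule anchors each signature to a single target sample per
  round; patient-specific idiosyncrasies enter the signature and are only
  removed by refinement, so disorders with one available sample keep
  noisier signatures.
* No calibrated probabilities: similarity ranks order candidates but carry
  no error rate.
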