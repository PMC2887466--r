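---
title: "Statistical methods for cytoblot RNAi screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for cytoblot RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

## The measurement problem

A genome-wide RNAi screen read out by an in-cell western ("cytoblot")
produces, for every well of every 384-well plate, two numbers: an
antibody-derived signal for a phospho-epitope (here called `pdakt`, for
phosphorylated *Drosophila* Akt) and a DNA-stain nuclear fluorescence
(`nucfl`) that serves as a relative cell-number proxy. Three properties
of these data drive every design decision in this package:

1. **The signal scales with cell number**, and RNAi perturbations change
   cell numbers severalfold, so raw signal differences mostly reflect
   viability, not pathway activity.
2. **Measurement noise is heteroscedastic in cell number**: wells with
   few cells are far noisier, on the log scale, than dense wells.
3. **Plates carry systematic artifacts**: edge effects tied to the well
   position, and batch offsets tied to the four 96-well source plates
   from which every 384-well screening plate is stamped.

The package implements two screen pipelines that address these problems
differently (reflecting the two detection chemistries used for the
stimulated and unstimulated screens), an external standard-curve method
for small follow-up experiments, and a synthetic-data generator that
reproduces the statistical structure the pipelines assume, with planted
effects and full ground truth.

## The insulin-screen pipeline

For the stimulated screen, each well's signal is first normalized to
cell number as `log2(pdakt / nucfl)`. Wells with a zero signal in either
channel cannot be normalized; they are flagged and excluded from
fitting, never imputed.

**Per-plate regression.** Within each plate the log ratio still trends
with cell number (dense wells saturate; the simulator encodes this as a
signal exponent `beta < 1`, making the expected log-ratio slope
`beta - 1` against `log2(nucfl)`). An ordinary least-squares regression
of the log ratio on `log2(nucfl)` is fitted per plate, and its residuals
carry forward. Because the fit is per plate, plate-to-plate gain and
intercept differences are absorbed here. OLS gives two exact algebraic
identities per plate -- residuals sum to zero and are orthogonal to the
covariate -- which the test suite asserts at `1e-9 * n`.

The covariate choice is a genuinely open design point: the downstream
error model is explicitly cell-number dependent, so we regress on
`log2(nucfl)` by default and expose raw `nucfl` as an option
(`covariate = "nucfl"`). Control wells are included in the fit by
default (`include_controls`), since nothing in the procedure requires
excluding them and most wells are samples anyway.

**The local error model.** All residuals of one genome-wide replicate
are pooled, and a locally weighted error model is fitted over the
cell-number covariate: for a query covariate `c`, the `k` nearest
training points by `|c_i - c|` (ties broken by the lower index in the
sorted training data) form the neighborhood; tricube weights
`w_i = (1 - (d_i/d_max)^3)^3` yield the local mean `m(c)` and the
reliability-weighted local standard deviation

    s(c)^2 = sum(w (v - m)^2) / (W - W2/W),   W = sum(w), W2 = sum(w^2),

which reduces to the ordinary `n-1` sample SD under uniform weights --
that exact reduction is what makes the model testable against global
statistics. The well's Z-score is `(residual - m(c)) / s(c)`: deviation
from the local average expressed in local SDs, so a fixed |Z| cutoff
spends the same false-positive budget at every cell density.

Numerical choices, all of which matter for exactness tests:

* `k` defaults to `max(200, 0.05 n)` -- large enough that estimation
  noise in `m` and `s` is negligible against the per-well noise, small
  enough to track the SD trend across the density range.
* Queries outside the training range clamp to the edge neighborhood.
  The model never extrapolates: density extremes are exactly where the
  assay is least reliable.
* `s(c)` is floored at `sd_floor = 1e-8` so Z-scores are always finite,
  which also defines the behavior of noise-free degenerate inputs
  (residuals of order machine epsilon produce Z of order `1e-6`, not
  `0/0`).
* The `k`-nearest set is located as a contiguous window in the sorted
  training data by a vectorized binary search; when tied covariate
  values cross the window's left edge the lower-index tie rule makes
  the true set non-contiguous, and those (rare) queries are recomputed
  exactly. The whole evaluator is checked against an independently
  coded brute-force implementation to `1e-12`.

**Position correction.** The mean Z of each of the 384 well positions,
taken across all plates of one replicate, estimates that position's
systematic effect (edge evaporation and the like); it is subtracted, so
every per-position mean becomes zero. The correction only subtracts --
no rescaling -- and is idempotent. With a single plate per replicate it
degenerates to all-zero Z, which is documented rather than prevented.

**Calling.** Off-target-flagged reagents (dsRNAs sharing 19 bp or more
with a non-target gene; the flag is an annotation input, not computed
here) are excluded from scoring and from result files. Per-amplicon Z is
averaged over the two screen replicates and thresholded at ±2.5:
suppressors below, enhancers above. The boundary is inclusive -- the
convention is not dictated by the procedure, so we chose inclusivity and
documented it.

## The baseline-screen pipeline

The unstimulated screen was dominated by a different artifact:
per-source-plate batch variation within each 384-well plate. Its
pipeline therefore works on the raw `pdakt/nucfl` ratios: each plate is
decomposed into its four interleaved 96-well quadrant groups, each group
is standardized to mean 0 / SD 1 (sample SD, `n-1`), the groups are
recombined, and the plate is Z-scored against its own mean and SD.
Standardization is affine-invariant, so *any* per-(plate, quadrant)
offset or gain -- however large -- is removed exactly; the test suite
asserts invariance of the final Z to planted offsets at `1e-10`.
Replicate averaging and a 3-SD cutoff finish the pipeline (enhancers
positive: increased phospho-signal without stimulation).

Two open points were settled as follows. The stamping pattern that maps
the four source plates onto the 384-well grid is taken as the standard
interleaved 2×2 parity convention (odd/odd, odd/even, even/odd,
even/even); group standardization is invariant to which labeling is
used as long as it matches the true stamping, and the convention is
isolated in `well_quadrant()`. Whether to standardize raw ratios or log
ratios is exposed as `use_log_ratio`; raw ratios are the default, log
ratios the robustness opt-in.

## External standards for follow-up experiments

Small experiments cannot estimate their own error model, so they are
scored against an external standard: 768 non-RNAi-treated wells spanning
the whole cell-density spectrum, one standard per stimulation condition
(`k = 64` by default, at least `2k` controls enforced). A treated well's
Z comes from the density-matched control mean and SD at its `nucfl`; by
construction the average untreated experiment of that condition scores
zero, which the tests assert (|mean self-Z| < 0.05 at n = 768).
Baseline and insulin standards are disjoint models and cross-scoring is
a hard error. Whether the standard models the raw signal or the ratio
is configurable (`value`); raw signal against raw `nucfl` is the
default, directly matching the idea of cell-number-dependent averages
and SDs. Treatment groups are compared by the classical pooled-variance
two-tailed t-test.

## What the simulator emulates -- and what it does not

`simulate_screen()` generates, per the default configuration, 58 plates
× 384 wells × 2 replicates × 2 conditions plus two 384-well untreated
standard plates per condition. On the log2 scale,

    log2(pdakt) = gain + beta * log2(nucfl) + S * [insulin] + pos(row, col)
                  + tau_cond * q(plate, quadrant, replicate)
                  + delta(amplicon, condition) + eps,
    eps ~ Normal(0, sigma0 + sigma1 / sqrt(nucfl / median)),

with `nucfl` log-normal. The defaults were fixed once, by a design-time
power analysis, to make one coherent operating point at which all of the
pipeline's claimed properties are simultaneously meaningful:

* `nucfl_sdlog = 0.6`: knockdowns change cell numbers severalfold; the
  wide density range is also what makes the per-plate slope estimable
  to ±0.05 on every plate.
* `sigma0 = sigma1 = 0.10`: a low-density well (tenth percentile) is
  roughly 1.4× noisier than a dense one -- heteroscedasticity strong
  enough that a global-SD Z-score measurably misallocates its
  false-positive budget, while a 4-SD effect remains recoverable at
  ≥95% after replicate averaging.
* `beta = 0.9` (mild saturation), `gain = 10`, insulin shift `S = 2`
  (a 4-fold stimulation), edge depression `0.15` log2 units on border
  wells.
* `tau_baseline = 0.3`, `tau_insulin = 0`: source-plate offsets are
  applied to the baseline condition, mirroring the fact that only the
  unstimulated screen (older detection chemistry) needed quadrant
  standardization; a faithful insulin pipeline has no quadrant
  correction, so nonzero insulin-side offsets would make it
  uncalibrated by construction rather than test anything.

**Planted effects.** Suppressors act in the insulin condition, enhancers
in the baseline condition, 200 each by default. Two non-obvious choices:

* Effect sizes are *self-consistent*: "planted at `n` SD" means `delta`
  solves `delta^2 = n^2 (v0 + f * delta^2)`, where `v0` is the no-hit
  pooled variance the pipeline sees and `f` the planted fraction --
  i.e. the stated multiple refers to the pooled dispersion of the
  screen *as measured*, which includes the hits' own contribution. With
  200 hits in 22,272 amplicons the naive definition falls ~12% short
  of its nominal multiple.
* Hits are placed spike-in style, at most one per (plate, quadrant)
  source group, as real screens distribute spike-in controls; this
  keeps a planted 96-well group's sample SD from being inflated by a
  second planted outlier. Default strength is a moderate 3 SD; the
  recovery benchmark plants 4-SD effects via `hit_strength_sd = 4`.

Two known-component panels (8 members scored by the insulin pipeline,
11 by the baseline pipeline) carry graded per-member effects chosen so
that recovery is deliberately partial -- illustrative of how a screen
reports recall against prior knowledge, not an estimate of any real
effect sizes. Off-target flags mark 5% of null amplicons; planted hits
and panel members are never flagged, so recovery measures the pipeline
rather than annotation attrition.

All randomness flows from one seeded stream in a fixed draw order whose
draw *counts* do not depend on amplitude parameters; sweeping
`tau_baseline` therefore reuses bit-identical noise, which is what lets
the batch-removal test demand `1e-10` agreement rather than statistical
similarity.

**What is not emulated:** imaging and antibody chemistry; correlation
between a reagent's effect on the pathway and its effect on cell number
(knockdown lethality is density variation in the simulator, but it is
independent of the planted effect); spatial noise correlation beyond
the deterministic edge term; and plate-order or temporal drift.
Passing tests therefore show that the pipelines do what they claim
under the stated noise model -- not that the model captures every
failure mode of real plates.

## Verification design

The test suite runs at two scales. Unit and property tests use small
synthetic inputs and independent oracles: a brute-force reimplementation
of the local error model, closed-form normal equations for the OLS,
closed-form t statistics, and exact algebraic identities. The
full-scale checks simulate complete screens (58 × 384 × 2; about 90,000
wells) and assert:

* null calibration -- the fraction of raw per-replicate |Z| ≥ 2.5 on a
  null screen falls in the exact-binomial 99% CI around
  `2 * pnorm(-2.5) = 0.0124`, and replicate averaging shrinks the tail;
* end-to-end recovery of 4-SD planted hits at the ±2.5 and 3.0 cutoffs
  (≥ 95% of 200 in each pipeline);
* exact removal of source-plate offsets up to twice the noise SD;
* per-plate slope recovery within ±0.05 on all 116 plates;
* a matched-FPR comparison in which the local error model's recall of
  the default 3-SD hits strictly exceeds a global-SD Z-score's. The
  comparison is made at an empirical FPR of 5×10⁻⁴ on true-null
  amplicons (the ~10 most extreme nulls define each threshold): the
  local model's advantage under constant log2 effects is a deep-tail
  property -- at shallow thresholds a global SD is genuinely not worse
  -- and 5×10⁻⁴ is the deepest tail whose empirical threshold is still
  estimable from ~21,000 nulls;
* follow-up calibration -- two null treatments at 7 replicates produce
  p < 0.01 in ≤ 5% of 1,000 simulated experiments.

The null screen used for calibration has planted effects *and*
systematic artifacts switched off (noise heteroscedasticity retained):
raw Z is computed before position correction, so any systematic term
would trivially inflate the tail without saying anything about the
error model's calibration.

## Known limitations

* The error model assumes residual noise is symmetric and roughly
  normal at each density; heavy-tailed contamination would call for a
  robust location/scale pair, which the procedure does not use.
* Position correction assumes the position effect is additive on the Z
  scale and constant across plates of a replicate; gradients that vary
  by plate are not removed (a median-polish/B-score approach would be,
  but is a different method).
* The baseline pipeline's group standardization assumes at least two
  distinct finite ratios per 96-well group and erases any true
  source-plate-wide biology together with the batch effect.
* Amplicons are the scoring unit throughout; gene-level aggregation
  across independent reagents is out of scope.
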