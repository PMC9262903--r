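---
title: "Radial-flow gaze pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-flow gaze pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowgaze)
```

flowgaze implements the computational core of a moving-AOI eye-tracking
design for studying how gaze responses to radial optic flow develop with
age: a random-dot flow-stimulus simulator, a gaze scorer, a synthetic cohort
generator, and the group-level mixed-model stage. This vignette documents
the models behind each stage, the parameters that matter, and the choices
made where the design was genuinely open.

## The stimulus model

A flow movie is a 30 frames/s, 10 s animation (300 frames) of 500 bright
dots on a 35.3° × 26.4° field. Dot speed follows the radial-flow rule

$$ \text{speed}(d) = k \cdot \mathrm{ecc}(d), $$

zero at the focus and growing linearly with eccentricity, with
k = 0.33 s⁻¹ (low speed) or 0.66 s⁻¹ (high speed). Each dot lives 10 frames
(333 ms) and respawns uniformly over the field when its lifetime expires or
it leaves the field. The focus starts 9.2° left or right of center and
sweeps to the mirror position and back over the 10 s trial.

Numerical choices:

* **Integration** is forward Euler at dt = 1/30 s, with both the speed and
  the radial direction re-evaluated each frame against the *instantaneous*
  focus position. Re-evaluation (rather than freezing a dot's direction at
  birth) is the only reading under which the radial pattern stays locked to
  a focus that moves.
* **Sweep speed** is fixed at v = 2·9.2/(T/2) = 3.68 °/s, the exact value
  for which the triangle trajectory closes at t = T; the nominal figure is
  ~3.7 °/s, but geometric closure is worth more than the rounded number.
* **Contraction** is produced *only* by playing an expansion frame set in
  reverse (`make_contraction()`), never by integrating inward motion, so the
  two directions contain bit-identical images in opposite order.
* **Degenerate dots**: a dot exactly at the focus has zero speed and an
  undefined direction; it stays in place.
* **Respawn** is evaluated after the motion step, and initial dot ages are
  staggered uniformly over the lifetime so respawns never synchronize.
* **Units**: all internal coordinates are degrees, origin at screen center,
  y upward; the single conversion constant 268 px / 9.2 deg ≈ 29.13 px/°
  (the AOI's own pixel correspondence) maps to raster pixels
  (`deg_to_px()`).

The *measured* mean dot speed of a simulated movie (`mean_dot_speed()`) is
about 4.2 °/s under the low-speed rule — the literal speed rule with dots
uniform over this field gives a lower whole-field average than the nominal
5.8 °/s figure sometimes quoted for such stimuli, whose averaging convention
is not defined. We therefore report the measured value and assert only the
exact 2:1 ratio between the high- and low-speed conditions.

## Gaze scoring

Gaze streams are 60 Hz samples (t, x, y, validity). The circular AOI
(diameter 9.2°) rides the focus trajectory; the whole-screen AOIW is the
background rectangle.

* **Looking time** is the count of valid in-AOI samples times 1/60 s. The
  sample weight is fixed: dropouts shorten the total rather than being
  interpolated, the simplest defensible convention given that no weighting
  scheme is canonical.
* **Latency** is the timestamp of the first valid in-AOI sample, censored at
  10 s when the AOI is never entered (including fully invalid or empty
  streams).
* **Boundary**: membership is inclusive (distance ≤ radius), with a 10⁻⁹ deg
  tolerance because the chance-geometry entry sample sits exactly on the
  boundary in exact arithmetic and must not flip with floating-point
  rounding.
* **Asymmetry index**: expansion looking time over the two-direction total,
  per speed condition; undefined (NA, excluded listwise) when a participant
  never looked at either stimulus, rather than imputed 0 or 0.5.

**Chance geometry.** For gaze pinned at screen center, the AOI's nearest
edge starts (9.2 − 4.6)° = 4.6° away (134 px) and approaches at 3.68 °/s
(107.2 px/s), so chance latency is 134/107.2 = 1.25 s; the 268 px AOI then
needs 2.5 s to cross the center, once outbound and once returning, so chance
looking time is 5 s. `chance_levels()` computes these from the geometry. At
the 60 Hz grid the four entry/exit times (1.25, 3.75, 6.25, 8.75 s) fall
exactly on samples; with the inclusive boundary both endpoints of each pass
count, so the discretized looking time is 302/60 ≈ 5.033 s — the analytic
5 s plus one boundary sample per pass — while latency is exactly 1.25 s.

## The synthetic cohort

No human data ship with the package; the cohort generator is the package's
own generative stand-in, built to exercise every downstream contract. It
emulates the study design — 13 age groups (1–12 years and adults) × 20
participants × 8 experimental trials (direction × speed × the two focus
paths, randomized order) plus 2 counterbalanced benchmark trials — and a
simple model of trial-level gaze:

1. a first orienting saccade lands at the AOI center after a lognormal
   latency (median by age and direction, σ = 0.5 on the log scale);
2. thereafter a two-state Markov chain per 60 Hz sample: *engaged* (gaze =
   AOI center + isotropic Gaussian jitter, SD 1°) versus *excursion* (a
   uniform off-AOI fixation point, held until the chain returns or the
   moving AOI overtakes it, in which case it is resampled);
3. i.i.d. dropouts at an age-dependent rate (12% at 1 year to 4% in
   adults).

The per-sample leave probability is 0.01; the return probability is not a
free dial but *calibrated*: `sample_participant()` inverts the closed-form
expected in-state occupancy of the chain over the trial horizon,
marginalized over the latency distribution by quantile quadrature, so that
the expected scored looking time equals the participant's target mean.
Participant heterogeneity is a single shared deviation per participant (one
normal shift, SD 0.8 s, on both directions' looking-time targets and one
lognormal scale, σ = 0.2, on both latency medians). The shared draw is
deliberate: it realizes exactly the random-intercept structure the
group-level model assumes, so the type-I behavior of the interaction tests
is meaningful. A direction-specific participant draw would inject a random
participant × direction effect the model does not represent and silently
inflate the interaction F — our replication suite flags exactly this if the
generator is changed.

The shipped presets (`behavior_presets()`) encode the developmental pattern
of interest: 1-year-olds look ~1.5 s longer at the contraction focus,
the bias reverses by age 5 (expansion bias of 1.0–1.6 s through adulthood),
and looking time for both directions is nondecreasing through ages 5–6
before plateauing. Every group's |expansion − contraction| difference is at
least 1 s so that a generating-truth *sign* is meaningful and recoverable at
n = 20. Benchmark trials use short, age-independent latency parameters
(median 0.9 s), mirroring a null age effect on basic gaze following.

What the generator does **not** emulate: saccade main-sequence dynamics,
smooth-pursuit gain, burst-like tracker dropout, head movement, or visual
salience gradients across the dot field. Passing tests therefore show that
the pipeline's measurement and inference machinery behaves correctly under
a controlled generative model — not that any specific developmental claim
holds in human data.

## Group-level statistics

The inferential stage mirrors a standard factorial mixed-model analysis:

* `fit_threeway_lmm()`: REML linear mixed model, fixed
  age × direction × speed factorial with sum-to-zero contrasts, participant
  random intercept, type-III F tests. Denominator df use **Kenward–Roger**
  by default, with **Satterthwaite** as a documented option/fallback; the
  result records which was used. Each term reports partial eta squared,
  η²ₚ = F·df₁/(F·df₁ + df₂), with a 95% CI from noncentral-F inversion
  (the confidence limits on the noncentrality parameter converted by
  ncp/(ncp + df₁ + df₂ + 1); the lower bound floors at 0, and for very
  small F the interval collapses to zero below the point estimate, as is
  standard for this construction).
* `simple_effects_by_age()`: expansion − contraction contrasts of
  least-squares means per age group (marginal over speed), signed so
  positive = expansion bias.
* `pairwise_ages()`: all 78 pairwise age contrasts within a direction; raw
  p-values are compared against the Bonferroni-corrected threshold
  0.05/78, matching the reporting convention of raw p with corrected α.
* `asymmetry_ttests()`: 26 two-tailed one-sample t-tests of the index
  against 0.5 (13 groups × 2 speeds) at α = 0.05/26, listwise-deleting
  undefined indices.
* `benchmark_anova()`: one-way age effect on benchmark latency. With
  trial-level input it fits the mixed model with a participant intercept;
  with one averaged row per participant that intercept is unidentifiable,
  so the function falls back to a fixed-effects one-way ANOVA and labels
  the result accordingly.
* `fit_twoway_lmm()`: the per-speed age × direction refit used to decompose
  a higher-order interaction, implemented as separate two-way models per
  speed level (contrasts within the full model are the noted alternative;
  refits match the described follow-up procedure).

Degenerate inputs short-circuit before model fitting: a constant response
returns F = 0, p = 1 for every term (an optimizer cannot be trusted on
zero-variance data), and single-level factors raise an explicit error.

Repetitions are averaged before modeling (4 condition means per
participant), matching the dependent-measure definition; modeling all 8
trials with a trial-level residual is possible by passing the unaveraged
score table but is not the default.

## Problem sizes and replication suites

The property suites run at sizes chosen to give stable Monte-Carlo
estimates on a single CPU: pipeline-closure and sign-recovery checks use
the full 13 × 20 design (50 seeded replications, Satterthwaite df inside
the loop — Kenward–Roger on a 52-parameter fixed-effects model is orders of
magnitude slower and numerically equivalent here at n = 1040 observations);
the type-I suite uses 200 replications of a reduced null cohort (6 groups ×
8 participants, both directions sharing one profile) and checks the
age × direction rejection rate against α = 0.05 within two binomial
standard errors. Oracle-equivalence checks compare the vectorized scorer
against a naive per-sample loop on 1000 random streams.

## Known limitations

* The dot simulator records coordinates, not rendered video; raster export
  of movies (codecs, luminance calibration) is out of scope, with
  luminance figures carried as metadata only.
* The generative gaze model is intentionally minimal; parameters are
  exposed so users can plug in their own presets, but conclusions about
  human cohorts require human data in the gaze TSV dialect.
* Chance levels assume the study's specific geometry (single lateral start
  offset, triangle trajectory); other trajectories need their own
  derivation.
* The η²ₚ confidence interval uses the noncentral-F construction on the
  mixed-model F with its approximate denominator df; it inherits the
  approximation error of that df.
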