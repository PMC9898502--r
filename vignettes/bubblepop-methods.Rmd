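---
title: "Methods: simulating and analysing a bubble-popping motor assessment"
author: "bubblepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a bubble-popping motor assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubblepop)
```

## The measurement model

The package models a 20-second window of a tablet game in which bubbles rise
along 5 vertical lanes and pop when the starting location of a touch lands
within 18.5 mm of the bubble's center. A popped bubble respawns from the
bottom of the same lane with the same character; a bubble that exits the top
is replaced by a random character. The device records touch traces and a
3-axis inertial stream at 60 Hz. Sessions in which the child touched the
screen fewer than 3 times are excluded as insufficiently engaged.

Coordinates are millimetres with the origin at the top-left corner, x
rightward and y downward, so a rising bubble has decreasing y. The default
screen is 160 x 220 mm, the portrait active area of a 10.2-inch tablet
class; all thresholds are metric, which is why millimetres are the native
unit. Pixel-to-mm conversion is the log producer's concern, not this
package's.

Several protocol details are not published and are therefore explicit
configuration with documented defaults (`game_config()`):

* **Bubble speed, 20 mm/s, one bubble per lane.** A bubble then takes 11 s
  to cross the screen, and a 20 s session offers roughly 10-20 realistic pop
  opportunities across the five lanes, the plausible range for the pop
  counts the assessment is designed around.
* **Pop boundary inclusive** (a touch at exactly 18.5 mm pops); switchable
  via `pop_boundary_inclusive` since the published rule does not state the
  boundary case.
* **Targeting radius 27.75 mm** (1.5 x pop radius): a touch this close to a
  bubble counts as *targeting* it even when it fails to pop. The assessment
  distinguishes "hit near or on a bubble" from popping without giving a
  number; the factor 1.5 is configurable.
* **Popping-accuracy decay 18.5 mm**: accuracy is 100% on the bubble disc
  and falls linearly to 0% at one decay length beyond the edge. Only the
  100% anchor and monotone decrease are specified publicly; the linear ramp
  is this package's choice, and the bubble's visual radius is identified
  with the pop radius.
* **Double-touch rule 0.3 s / 10 mm**: touch *i+1* is a double touch when it
  starts within 0.3 s of touch *i*'s offset and within 10 mm of touch *i*'s
  onset location. "Tried to double touch" is otherwise undefined; both
  constants are configurable.
* **Exploration grid 10 mm**: the exploration percentage is the fraction of
  10 mm screen cells (partial edge cells count) containing at least one
  touch sample.

## The synthetic agent and cohort generator

The agent (`agent_profile()`) is an event loop over the session window. It
picks a target — with probability `repeat_prob` the respawn of the bubble it
just popped, otherwise the nearest on-screen bubble — and aims at the
target's instantaneous center with isotropic Gaussian error (`aim_sd_mm`).
Each touch has a lognormal duration (parameterised by its own mean and SD)
and drags along a smooth random walk whose total path length is
gamma-distributed with mean `path_length_scale_mm`; gaps between touches are
exponential with mean `inter_touch_mean_s`; attempts per target are
geometric (support >= 1) with mean `touches_per_target_mean`; with
probability `double_touch_prob` a touch is followed by a rapid second tap
nearby. A touch pops the nearest on-screen bubble if its onset lies within
the pop radius, which triggers the same-character respawn. The inertial
stream is gravity plus white noise plus a Gaussian impulse at each touch
onset (peak `force_scale` m/s^2, +/-2 SD width 80 ms) on the axis normal to
the screen.

These distributional families (Gaussian aim error, lognormal durations,
geometric attempts, exponential gaps) are deliberately minimal-assumption
choices; every one of them is a profile parameter, not a constant.

The two built-in profiles (`default_profiles()`) encode the group contrasts
the assessment is designed to detect: the case profile has 50% larger aim
error, 50% longer touch durations and 50% longer drag paths than the
NT-like profile, plus mildly higher perseveration and double-touching. With
the default geometry this gives per-attempt pop probabilities of about 0.93
(NT) versus 0.70 (case), so the case group pops at a visibly lower rate
despite similar touch counts.

Cohorts (`cohort_spec()`, `simulate_cohort()`) add three layers on top of
the group profiles:

1. **Age structure.** Ages are uniform over the cohort range (default 18-36
   months). Profile parameters shift linearly per month, centered on the
   range midpoint, with defaults that make older children faster, more
   accurate and more active (negative slopes on aim error, touch duration,
   path length and inter-touch gap). Adjusted parameters are clipped to
   their legal domains.
2. **Person-to-person jitter.** Each participant's kinematic parameters are
   multiplied by lognormal jitter with coefficient of variation 0.15. This
   matters: without it, within a group the latent skill would be a
   deterministic function of age, and every age-controlled partial
   correlation with clinical scores would be zero by construction.
3. **Clinical scores.** Latent skill is minus the standardized (cohort-wide)
   age-adjusted aim error; each score is `loading x skill + N(0, noise_sd)`.
   The linear-Gaussian form makes partial-correlation recovery analytically
   predictable: a zero loading gives zero population partial correlation,
   and a positive loading gives a negative partial correlation with
   aim-driven features such as distance to center.

All randomness flows from a single integer seed; sessions, cohorts, LOOCV
folds and pipeline artifacts are pure functions of their inputs and seed.

### What the simulator does and does not emulate

The generator reproduces the *structure* of real sessions — lane dynamics
with same-character respawn, engagement heterogeneity, age trends,
group-level contrasts in accuracy, tempo and variability, score-feature
coupling — but not the messiness of real toddler data: no caregiver
interference, no device repositioning, no attention lapses mid-window, no
training phase (records represent only the analysed 20 s window), and
touch physiology reduced to a few parametric families. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* is correct and
calibrated (type-I error, coverage, recovery of planted effects at
generator-set effect sizes), not that any particular real-data effect size
will be reproduced.

## Feature extraction conventions

The 19 families expand to 37 session values (`feature_names()`). Choices
that the published definitions leave open, as implemented here:

* Standard deviations are sample SDs (n-1); medians use the
  midpoint-of-two convention; every std summary is NA (never 0) below two
  observations, and ratio features are NA when their denominator is empty
  (e.g. popping rate with zero touches, repeat percentage with fewer than
  two pops).
* A *target episode* is a maximal run of consecutive touches assigned to
  the same bubble track (nearest on-screen bubble within the targeting
  radius at onset). The episode spans its first touch's onset to its last
  touch's offset; that span is `time_on_target`, and `touch_frequency` is
  touches per second of span (NA for zero-duration single-sample episodes).
  A respawned bubble is a new track, so pops and exits end episodes
  naturally.
* Popping accuracy is evaluated per sample of each *targeted* touch
  against the episode's bubble at the sample's timestamp, with the bubble's
  position clamped to its track interval (frozen at the pop location once
  popped). Untargeted touches have no reference bubble and contribute
  nothing to accuracy features.
* The applied-force proxy removes gravity with a 1-second running median
  per axis (constant end extension) and integrates the squared magnitude of
  the residual over the touch window by the trapezoid rule. Touches shorter
  than the sampling step use a one-sample rectangle; an interior gap in the
  stream larger than 3 sampling steps is an error. This high-pass +
  trapezoid construction is an approximation chosen here; the original
  device-side algorithm is not public.
* `repeat_percentage` counts consecutive pop pairs with the same lane *and*
  character over (pops - 1); `number_of_transitions` counts consecutive pop
  pairs in different lanes.
* Average time to pop a bubble is not a separate feature: it is
  `time_on_target` restricted to episodes that end in a pop.

## Statistical conventions

* **ANCOVA** is the least-squares fit `y ~ covariates + group` with the
  group term tested added last (type-II; order-invariant here because the
  model has a single categorical predictor and no interactions). Rows with
  any missing value are dropped listwise. Eta-squared is **classical**
  (`SS_group / SS_total`) by default — the conventional small/middle/large
  anchors (.01/.04/.14) assume it — with partial eta-squared available via
  `eta = "partial"`. With no covariates the fit reduces exactly to textbook
  one-way ANOVA, which the tests verify to 1e-10.
* **BH adjustment** uses the standard step-up formulation
  (`stats::p.adjust`). Features whose ANCOVA cannot run (all-missing,
  degenerate fit, a group below 2 observations) are reported as skipped and
  excluded from the BH family. Note that BH-adjusted values are *not* a
  fixed point of re-adjustment — `p = (0.01, 0.5)` adjusts to
  `(0.02, 0.5)` and again to `(0.04, 0.5)` — so the tests assert the
  meaningful invariants instead: monotonicity in the sorted order and exact
  agreement of the rejection set with the classical step-up rule.
* **Mann-Whitney** uses midranks; the p-value is exact when the combined
  sample size is at most 20 with no ties, otherwise a tie- and
  continuity-corrected normal approximation. The rank-biserial effect size
  is `1 - 2U/(n1 n2)` with U counting pairs where the first sample exceeds
  the second (ties half).
* **Partial Spearman** is rank-then-partial: rank-transform x, y and
  covariates with midranks, residualise the ranked x and y on the ranked
  covariates plus intercept, and correlate the residuals; significance uses
  the Student-t transform with `n - 2 - k` degrees of freedom. The
  alternative (computing Spearman on residuals of the raw variables) is not
  what this package does; with no covariates the implementation collapses
  to plain Spearman exactly.
* The two-sample **proportion z-test** uses the pooled variance; it is
  degenerate only when the pooled proportion is 0 or 1.

## Classifier evaluation

Discrimination between two groups is evaluated with pooled leave-one-out
cross-validation: each sample is scored by a logistic regression trained on
all others, and one ROC/AUC is computed from the pooled held-out scores
(with one-sample folds, pooling is the only coherent way to build a curve).
Inside each training fold, in order: the minority class is up-sampled with
replacement to parity (fold-seeded); hyperparameters — C log-spaced in
[0.01, 100], penalty in {l1, l2, none}, intercept on/off — are selected by
pooled stratified inner-CV AUC (3 folds); features are standardized with
training-fold statistics; the model is refit and the held-out sample
scored. The hyperparameter search is fully nested inside LOOCV: selecting
once on all data would leak the held-out label into the selection step, so
the package does not offer that variant.

The solver contract is "reach the penalized-likelihood optimum": L2 and
unpenalized fits use a Newton/IRLS solver (checked in the tests against glm
and glmnet to high precision), L1 fits use the glmnet coordinate-descent
path. Solver-specific grid entries of any one library (dual formulations,
solver names) are deliberately not part of the interface.

Greedy forward selection starts from the single feature with the best
pooled LOOCV AUC and adds whichever feature most improves it, up to
`max_features` (default 3), breaking ties by canonical column order; each
step carries a Hanley-McNeil 95% confidence interval computed from the
class counts.

## Numerical and I/O choices

* Session JSON is written with 17 significant digits, so
  `read_session(write_session(r))` reproduces `r` exactly and a re-write is
  byte-identical; the schema is versioned (`schema_version: 1`) and unknown
  top-level fields round-trip through the `meta` bag.
* Pop detection resolves ties (two bubbles exactly equidistant) in favour
  of the earlier track in schedule order.
* The cohort YAML uses `n_participants` (a bare `n` key is a YAML 1.1
  boolean).
* Degenerate inputs are errors, not silent NAs, where they indicate a
  broken analysis: constant response in ANCOVA, single-class labels in ROC,
  zero-variance inputs to partial correlations.

## Problem sizes used by the test suite

The acceptance-level checks run at the following sizes, chosen to make
Monte-Carlo bands tight enough to be meaningful: feature-oracle equivalence
on 50 randomized 6-second sessions; type-I calibration on 500 null cohorts
of n = 60/60 with the rejection fraction pooled across the ANCOVA family
(the per-feature binomial noise at 500 replicates is about +/-1 percentage
point, so the pooled fraction is the stable calibration summary);
Hanley-McNeil coverage at true AUC 0.7 with n = 50/50 over 1,000
replicates; BH-power recovery of a +50% aim-error effect over 50 cohorts of
n = 60/60; greedy-selection recovery of 2 planted features (standardized
shift 1.5) among 5 noise features at n = 40/40 over 20 seeds, with a
reduced hyperparameter grid (C in {0.01, 1, 100}, penalties {l2, none},
intercept on) and `max_features = 2`; and a 25-seed permuted-label leakage
check. The full 9-point C grid with all penalties remains the default for
analysis use.

## Known limitations

* The simulator's touch traces are smooth random walks; real finger
  trajectories have structured sub-movements, so absolute values of
  path-length and velocity features should not be compared to real data.
* The force proxy depends on the (unpublished) device-side filtering; only
  its qualitative behaviour — zero without impulses, increasing with impulse
  amplitude — transfers.
* Three-group cohorts are analysed as pairwise designs; there is no omnibus
  three-level test, matching the pairwise study design this pipeline
  mirrors.
* ANCOVA assumes additive covariate effects; no interaction or matching
  machinery is provided (matching is a cohort-construction concern).
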