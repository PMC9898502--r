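# bubblepop

Simulation and motor-feature analysis of a tablet bubble-popping game.

Short touchscreen games are an attractive way to measure visual-motor skill
in very young children: they need no language, no special equipment, and can
be administered at scale in primary-care settings. In one widely used design,
bubbles rise along five vertical lanes for a 20-second window; a bubble pops
when the starting location of a touch lands within 18.5 mm of its center,
and a popped bubble respawns in the same lane with the same cartoon
character (so repetitive versus exploratory play is observable). The
device's 60 Hz touch and inertial streams are distilled into 19 families of
motor features — popping rate, distance to the bubble center, touch
duration/length/velocity, an applied-force proxy from the accelerometer,
popping-accuracy scores, targeting structure — which differ between
neurotypical and autistic children and correlate with standardized clinical
assessments of fine motor and cognitive ability.

`bubblepop` implements that entire analysis chain as tested, reusable R
code, together with a synthetic game-and-agent simulator so that every stage
can be exercised, calibrated and power-tested without access to restricted
participant data:

* **Session data model** (`session_record`, `read_session`,
  `write_session`, `validate_session`, `qc_filter`): JSON session logs with
  full invariant validation and the engagement rule that excludes sessions
  with fewer than 3 touches.
* **Simulator** (`simulate_bubbles`, `simulate_agent_touches`,
  `simulate_session`, `simulate_cohort`): five-lane bubble dynamics with
  same-character respawn, a parametric child agent (isotropic aim error,
  lognormal touch durations, random-walk finger drags, geometric re-attempts,
  perseveration), age-structured and person-jittered parameters, and a
  linear-Gaussian clinical-score model on a latent motor-skill variable.
* **Feature extraction** (`extract_features`, `features_table`): the 19
  feature families (37 session-level values).
* **Group statistics** (`ancova_compare`, `compare_all`, `bh_adjust`,
  `mannwhitney_rb`, `proportions_ztest`, `spearman_partial`,
  `correlate_features`): one-way ANCOVA with eta-squared and
  Benjamini-Hochberg FDR control, Mann-Whitney U with rank-biserial effect
  sizes, proportion z-tests, and age-adjusted partial Spearman correlations.
* **Classifier evaluation** (`greedy_select`, `loocv_scores`, `roc_auc`,
  `hanley_mcneil_ci`): greedy forward feature selection maximising pooled
  leave-one-out cross-validated AUC, with nested hyperparameter search,
  minority up-sampling inside training folds, and Hanley-McNeil confidence
  intervals.
* **Pipeline** (`run_pipeline`, `make_report`): simulate -> QC -> features
  -> compare/correlate/classify with deterministic, manifest-tracked
  artifacts.

## The statistics at the core

For a feature $y$ and diagnostic group $g$ with covariates $z$ (age, or age
and IQ), group differences use the one-way ANCOVA F-test of $g$ added last
to $y \sim z + g$, with classical effect size
$\eta^2 = SS_{group}/SS_{total}$, and Benjamini-Hochberg adjustment across
the feature family. Feature-clinical associations use partial Spearman
correlations (Pearson correlation of rank residuals after regressing the
ranked variables on ranked covariates), tested with
$t = \rho\sqrt{(n-2-k)/(1-\rho^2)}$. Group discrimination uses logistic
regression scored by pooled LOOCV AUC with greedy forward selection; AUC
uncertainty uses the Hanley-McNeil standard error
$SE^2 = [A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)]/(n_+ n_-)$ with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$.

## Worked example

```r
library(bubblepop)

prof <- default_profiles()                    # NT-like and case-like agents
spec <- cohort_spec(
  groups = list(NT = list(profile = prof$nt, n = 30),
                autistic = list(profile = prof$case, n = 30)),
  clinical_score_model = list(fine_motor = c(6, 3)),
  seed = 42)

cohort <- simulate_cohort(spec)
kept <- qc_filter(cohort$sessions)$kept
ft <- features_table(kept)
res <- compare_all(ft, group = "group", covariates = "age_months")
print(res)
```

```
Covariate-adjusted group comparisons (BH-adjusted across 37 features)
                   feature     F df_effect df_error     p_raw p_adjusted eta_squared n_used skipped_reason
         touch_length_mean 73.05         1       57 8.550e-12  1.582e-10      0.5211     60           <NA>
       touch_length_median 74.32         1       57 6.459e-12  1.582e-10      0.5345     60           <NA>
       touch_duration_mean 65.96         1       57 4.315e-11  5.321e-10      0.4437     60           <NA>
       bubble_popping_rate 55.43         1       57 5.757e-10  4.335e-09      0.4628     60           <NA>
     touch_duration_median 55.37         1       57 5.859e-10  4.335e-09      0.3880     60           <NA>
    touches_per_target_std 49.96         1       57 2.451e-09  1.512e-08      0.4569     60           <NA>
        applied_force_mean 44.86         1       57 1.012e-08  5.351e-08      0.3505     60           <NA>
   distance_to_center_mean 37.84         1       57 8.115e-08  3.753e-07      0.3183     60           <NA>
 ...
31 features significant at FDR 0.05
```

The case group drags its finger farther and longer, pops bubbles at a lower
rate, and lands farther from bubble centers — the contrasts the generator
plants and the battery is designed to detect (F values this large reflect
the deliberately strong default group separation; a null cohort with both
groups given the same profile leaves the table empty of BH-significant rows
at the expected false-discovery rate).

Classification on the same cohort:

```r
labels <- factor(ft$group, levels = c("NT", "autistic"))
trace <- greedy_select(ft[, c("touch_length_mean", "touch_duration_mean",
                              "time_on_target_mean", "distance_to_center_mean",
                              "number_of_targeted_bubbles",
                              "screen_exploratory_percentage")],
                       labels, classifier_spec(seed = 42, max_features = 3))
print(trace)
#> Greedy forward selection by pooled LOOCV AUC
#>   step 1: + touch_length_mean            AUC 0.933 (95% CI 0.867-1.000)
#>   step 2: + time_on_target_mean          AUC 0.984 (95% CI 0.952-1.000)
#>   step 3: + distance_to_center_mean      AUC 0.992 (95% CI 0.970-1.000)
```

## Vignette

`vignettes/bubblepop-methods.Rmd` describes the generative model, the
feature definitions and their edge cases, the statistical conventions
(eta-squared variant, exact-test switches, tie handling), the classifier
evaluation design, and what the synthetic cohorts do and do not say about
real data.
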