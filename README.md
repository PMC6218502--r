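# fallrisk

Multifactorial fall-risk assessment from body-worn inertial sensors.

Community-dwelling older adults are screened for fall risk with a
seven-subtest battery recorded by five 9-DOF inertial sensors (low back,
both upper legs, both lower legs; 100 Hz) plus two tablet tasks:

| Subtest | Sensor(s) | Representative measures |
|---|---|---|
| Sensory integration (SIT): quiet standing, eyes open/closed × firm/foam | low back | equilibrium score, RMS & jerk of acceleration/angular velocity, spectral measures (AP/ML) |
| Limits of stability (LOS): forward reach | low back | reach distance, RMS & jerk of angular velocity |
| Five-times sit-to-stand (STS5) | upper leg | transition durations, angular velocity, jerk |
| Timed up and go (TUG) | low back + both lower legs | gait velocity, step time/length, turning time & angular velocity |
| Motor function (MF) | upper + lower leg | knee flexion/extension range of motion |
| Choice reaction (CRT) | app log | information processing speed, simple reaction time |
| Falls efficacy scale (FES) | app log | questionnaire score |

The package implements the full analysis chain:

1. **Signal processing** — zero-phase 4th-order low-pass Butterworth
   (20 Hz cutoff; two-pass magnitude `1/(1+(f/fc)^8)`), numerical
   derivatives, gravity-based trunk tilt.
2. **Feature extraction** — a declarative 155-measure catalogue
   (`measure_catalogue()`) drives `extract_all()`. Gait events come from
   shank angular velocity: mid-swing = high peak per cycle, toe-off /
   heel-strike = flanking troughs; the TUG turn is the swing-free gap
   between the walking halves. STS5 cycles are segmented from the thigh's
   biphasic angular-velocity pulses at 10% of the per-cycle peak.
   Equilibrium score = `100·(1 − sway range/12.5°)`, clamped to [0, 100].
3. **Screening** — per-measure pooled two-sample t-tests (faller vs
   non-faller) and empirical ROC AUC with Hanley–McNeil CIs; a measure is
   selected when significant on both (`screen_measures()`), then ranked by
   random-forest mean decrease accuracy (`rank_measures()`).
4. **Classification** — six models (logistic regression, Gaussian naive
   Bayes, CV-pruned decision tree, gradient-boosted trees, random forest,
   RBF-kernel SVM) under repeated stratified 10-fold cross-validation with
   faller as the positive class (`evaluate_model()`, `compare_models()`).
5. **Synthetic data** — generators with ground truth for every stage:
   `simulate_tug()`, `simulate_sway()`, `simulate_sts5()`, `simulate_mf()`,
   `simulate_los()`, app-log simulators, `simulate_cohort_features()`
   (feature-level cohorts from published group means/SDs at n = 114/82),
   and `simulate_battery()` (whole signal-level cohorts).

The classifiers, CART/forest/boosting engines (Rcpp) and the SVM dual
solver (`quadprog`) are implemented in the package, so it runs with a
plain base-R + Rcpp + jsonlite + quadprog stack.

## Worked example

```r
library(fallrisk)

# simulate one TUG trial with realistic noise and recover the gait events
sim <- simulate_tug(gait_profile(n_steps = 12, stride_time = 1.05,
                                 noise_sd = 10), seed = 1)
ev <- detect_gait_events(sim$session$recordings$left_lower_leg,
                         sim$session$recordings$right_lower_leg)
ev <- detect_turn(ev, sim$session$recordings$low_back)
gm <- gait_measures(ev, sim$session$recordings$low_back, walkway_distance = 3)
round(unlist(gm[c("tug_gait_velocity", "tug_step_time", "tug_step_length",
                  "tug_turn_time")]), 3)
#> tug_gait_velocity     tug_step_time   tug_step_length     tug_turn_time
#>             1.036             1.048             0.500             2.110
```

Gait velocity is total distance (2 × 3 m) over walking time excluding the
turn; step time is the same-foot toe-off interval (so it matches the
scheduled 1.05 s stride); the turn time recovers the profile's 2.11 s.

```r
# feature-level cohort at the published group statistics, then screen
df <- simulate_cohort_features(cohort_spec(seed = 1))
scr <- screen_measures(df)
sum(scr$selected)
#> [1] 35
sel <- scr[scr$selected, c("measure_id", "p", "auc")]
head(sel[order(-sel$auc), ], 3)
#>                        measure_id            p       auc
#>                         fes_score 3.319665e-15 0.8076594
#>                 tug_gait_velocity 3.015758e-12 0.7613393
#>  crt_information_processing_speed 2.521951e-10 0.7556697

# six-model cross-validated classification on the screened measures
folds <- make_folds(df$fall_status, k = 10, repeats = 2, seed = 1)
ev <- evaluate_model(model_spec("svm"), df, folds,
                     measures = scr$measure_id[scr$selected])
ev
#> <model_evaluation> svm (2 repeat(s)): accuracy 95.42 +/- 4.66%,
#>   sensitivity 93.12 +/- 8.58%, specificity 96.93 +/- 5.87%
```

(Accuracies on a synthetic cohort of independent normals are not expected
to reproduce the published cohort's values; see the methods vignette.)

End-to-end demo (simulate → extract → screen → classify → report):

```r
res <- run_pipeline(pipeline_config(n_nonfaller = 10, n_faller = 10, seed = 1))
```

or from the shell: `exec/fallrisk run-all --seed 1 --out demo_out`.

## Vignette

`vignettes/fallrisk-methods.Rmd` documents the model and algorithms, every
tunable default, what the synthetic generators do and do not emulate, and
the known limitations (including the one deliberately red acceptance
check).
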