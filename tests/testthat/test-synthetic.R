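test_that("simulators are deterministic given the seed", {
  a <- simulate_tug(gait_profile(noise_sd = 10), seed = 7)
  b <- simulate_tug(gait_profile(noise_sd = 10), seed = 7)
  expect_identical(a$session$recordings$low_back$gyro,
                   b$session$recordings$low_back$gyro)
  expect_identical(a$truth, b$truth)
  c1 <- simulate_cohort_features(cohort_spec(seed = 3))
  c2 <- simulate_cohort_features(cohort_spec(seed = 3))
  expect_identical(c1, c2)
})

test_that("tug generator honours its stated schedule", {
  sim <- simulate_tug(gait_profile(n_steps = 10, stride_time = 1.0), seed = 1)
  tr <- sim$truth
  # turn window sits between the walking halves, swing-free inside
  all_ms <- c(tr$left$mid_swing, tr$right$mid_swing)
  inside <- all_ms > tr$turn_start & all_ms < tr$turn_end
  expect_false(any(inside))
  expect_equal(tr$turn_duration, 2.11, tolerance = 1e-9)
  # event ordering within each cycle
  for (leg in c("left", "right"))
    expect_true(all(tr[[leg]]$toe_off < tr[[leg]]$mid_swing &
                    tr[[leg]]$mid_swing < tr[[leg]]$heel_strike))
  # peak sample lands on the scheduled time (noiseless)
  rec <- sim$session$recordings$right_lower_leg
  pk <- rec$time[which.max(rec$gyro[, "y"] *
                           (rec$time < tr$turn_start - 0.2))]
  expect_lte(min(abs(pk - tr$right$mid_swing)), 0.0101)
  # over-long turn is rejected
  expect_error(simulate_tug(gait_profile(n_steps = 6, turn_duration = 60,
                                         walkway_distance = 1)),
               "spec error")
})

test_that("tug step-time ground truth tracks the profile at large n", {
  for (st in c(1.04, 1.08)) {
    sim <- simulate_tug(gait_profile(n_steps = 60, stride_time = st,
                                     stride_time_sd = 0.05,
                                     walkway_distance = 15), seed = 11)
    expect_lt(abs(sim$truth$step_time - st), 0.01 * st)
  }
})

test_that("sway generator hits its RMS targets through extraction", {
  sw <- simulate_sway(sway_profile(rms_acc_ap = 0.02, rms_acc_ml = 0.007),
                      "SIT_EO_FOAM", seed = 2)
  acc <- sw$session$recordings$low_back$acc
  # realized RMS of the emitted signal is exact
  expect_lt(abs(sqrt(mean((acc[, 1] - mean(acc[, 1]))^2)) - 0.02), 1e-12)
  m <- fallrisk:::extract_sit_condition(sw$session)
  expect_lt(abs(m$sit_eo_foam_rms_acc_ap - 0.02), 5e-9)
  expect_lt(abs(m$sit_eo_foam_rms_acc_ml - 0.007), 5e-9)
  # ground-truth jerk recoverable by the independent extractor
  expect_equal(m$sit_eo_foam_jerk_acc_ap, sw$truth$jerk_acc_ap,
               tolerance = 0.02)
  # zero-noise request: flat signal
  sw0 <- simulate_sway(sway_profile(rms_acc_ap = 0, rms_acc_ml = 0,
                                    rms_gyro_ap = 0, rms_gyro_ml = 0),
                       seed = 3)
  expect_equal(rms_amplitude(sw0$session$recordings$low_back$acc[, 1]), 0)
})

test_that("sway spectral content respects the stated bandwidth", {
  sw <- simulate_sway(sway_profile(bandwidth = 2, rms_acc_ap = 0.02),
                      seed = 4)
  fm <- frequency_measures(sw$session$recordings$low_back$acc[, 1], 100)
  below <- sum(fm$psd[fm$freq <= 4]) / sum(fm$psd)
  expect_gt(below, 0.99)
})

test_that("sts5 generator validates its schedule", {
  expect_error(simulate_sts5(rep(2, 4)), "exactly 5")
  expect_error(simulate_sts5(c(2, 2, 2, 2, -1)), "positive")
  st <- simulate_sts5(rep(2, 5), seed = 1)
  expect_equal(st$truth$sit_stand_sit, rep(2, 5), tolerance = 1e-12)
})

test_that("cohort features reproduce the group parameters", {
  spec <- cohort_spec(seed = 5)
  df <- simulate_cohort_features(spec)
  expect_equal(nrow(df), 196)
  expect_equal(sum(df$fall_status == "faller"), 82)
  expect_equal(ncol(df), 2 + 155)
  # FES realized group means within 3 SE of the spec
  nf <- df$fes_score[df$fall_status == "non_faller"]
  f <- df$fes_score[df$fall_status == "faller"]
  expect_lt(abs(mean(nf) - 9.73), 3 * 2.98 / sqrt(114))
  expect_lt(abs(mean(f) - 14.96), 3 * 4.92 / sqrt(82))
  # effect-direction fidelity for every printed or synthetic contrast
  st <- spec$stats[spec$stats$source != "null", ]
  for (i in seq_len(nrow(st))) {
    id <- st$measure_id[i]
    d_spec <- st$f_mean[i] - st$nf_mean[i]
    d_obs <- mean(df[[id]][df$fall_status == "faller"]) -
      mean(df[[id]][df$fall_status == "non_faller"])
    expect_equal(sign(d_obs), sign(d_spec), info = id)
  }
})

test_that("unknown measures and bad SDs are rejected", {
  st <- default_measure_stats()
  st$measure_id[1] <- "no_such_measure"
  expect_error(cohort_spec(stats = st), "not in catalogue")
  st2 <- default_measure_stats()
  st2$nf_sd[3] <- 0
  expect_error(cohort_spec(stats = st2), "SDs must be positive")
})

test_that("identical group distributions give chance-level AUC", {
  st <- default_measure_stats()
  st$f_mean <- st$nf_mean
  st$f_sd <- st$nf_sd
  df <- simulate_cohort_features(cohort_spec(stats = st, seed = 17))
  rc <- roc_auc(df$fes_score, df$fall_status)
  expect_lt(rc$auc, 0.58)  # oriented AUC; chance plus sampling noise
})

test_that("per-subject streams are individually reproducible", {
  spec <- cohort_spec(n_nonfaller = 5, n_faller = 5, seed = 21)
  df1 <- simulate_cohort_features(spec)
  spec2 <- cohort_spec(n_nonfaller = 5, n_faller = 3, seed = 21)
  df2 <- simulate_cohort_features(spec2)
  # first eight subjects unchanged when the cohort is truncated
  expect_equal(df1[1:8, names(df2)], df2[1:8, ], tolerance = 1e-12)
})

test_that("demographics reproduce the faller rule and group stats", {
  demo <- simulate_demographics(114, 82, seed = 13)
  expect_equal(unname(table(demo$fall_status)["faller"]), 82)
  expect_equal(demo$fall_status,
               classify_fall_status(demo$n_falls_past_year,
                                    demo$injurious_fall == 1))
  expect_lt(abs(mean(demo$age[demo$fall_status == "non_faller"]) - 72.02),
            3 * 4.17 / sqrt(114))
})
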