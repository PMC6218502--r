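test_that("rms and jerk follow the sway conventions and closed forms", {
  rate <- 100
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)        # whole periods
  expect_equal(rms_amplitude(rep(4.2, 100)), 0)
  expect_equal(rms_amplitude(sin(2 * pi * 2 * t)), 1 / sqrt(2),
               tolerance = 1e-3)
  expect_error(rms_amplitude(numeric(0)), "empty")
  expect_equal(jerk_measure(rep(1, 100), rate), 0)
  # ramp: derivative constant, mean-removed RMS 0; raw variant returns |k|
  ramp <- 3 * t
  expect_equal(jerk_measure(ramp, rate), 0, tolerance = 1e-9)
  expect_equal(jerk_measure(ramp, rate, mean_removed = FALSE), 3,
               tolerance = 1e-9)
  # unit 2 Hz sinusoid: jerk RMS = 2*pi*2/sqrt(2) = 8.886
  expect_equal(jerk_measure(sin(2 * pi * 2 * t), rate), 2 * pi * 2 / sqrt(2),
               tolerance = 0.01 * 8.886)
})

test_that("rms and jerk are scale-equivariant and shift-invariant", {
  set.seed(42)
  rate <- 100
  x <- butterworth_lowpass(rnorm(1000), rate, 5)
  for (k in c(0.3, 2, 17)) {
    expect_equal(rms_amplitude(k * x), k * rms_amplitude(x), tolerance = 1e-12)
    expect_equal(jerk_measure(k * x, rate), k * jerk_measure(x, rate),
                 tolerance = 1e-12)
  }
  expect_equal(rms_amplitude(x + 5), rms_amplitude(x), tolerance = 1e-12)
})

test_that("frequency measures locate tones and spectral centroids", {
  rate <- 100
  t <- seq(0, 30, by = 1 / rate)
  bin <- rate / 256
  fm <- frequency_measures(sin(2 * pi * 3 * t), rate)
  expect_lt(abs(fm$median_freq - 3), bin)
  expect_lt(abs(fm$centroid_freq - 3), bin)
  # equal-power tones at 2 and 6 Hz: centroid at 4 Hz
  fm2 <- frequency_measures(sin(2 * pi * 2 * t) + sin(2 * pi * 6 * t), rate)
  expect_lt(abs(fm2$centroid_freq - 4), bin)
  # total power of a unit sinusoid is its variance 1/2
  expect_equal(fm$total_power, 0.5, tolerance = 0.05)
  expect_error(frequency_measures(rnorm(100), rate), "length error")
})

test_that("equilibrium score is linear in sway range and clamped", {
  expect_equal(equilibrium_score(rep(0, 100)), 100)
  expect_equal(equilibrium_score(c(0, 12.5)), 0)
  expect_equal(equilibrium_score(c(0, 0.25 * 12.5)), 75)
  expect_equal(equilibrium_score(c(-20, 20)), 0)  # clamped at 0
  expect_error(equilibrium_score(numeric(0)), "empty")
  expect_error(equilibrium_score(1:3, theta_limit = -1), "positive")
})

test_that("sensory-system ratio scores follow the convention", {
  es <- c(eo_firm = 95, ec_firm = 95, eo_foam = 95, ec_foam = 95)
  expect_equal(sensory_system_scores(es), c(som = 100, vis = 100, vest = 100))
  es["eo_foam"] <- 82
  expect_equal(sensory_system_scores(es)[["vis"]], 100 * 82 / 95,
               tolerance = 1e-10)
  es["ec_foam"] <- 0
  expect_equal(sensory_system_scores(es)[["vest"]], 0)
  expect_true(all(is.na(sensory_system_scores(
    c(eo_firm = 0, ec_firm = 90, eo_foam = 90, ec_foam = 90)))))
  expect_error(sensory_system_scores(c(eo_firm = 90)), "missing condition")
})

test_that("gait events on noiseless simulations match ground truth", {
  sim <- make_tug_session(seed = 1, n_steps = 10, stride = 1.0)
  s <- sim$session
  ev <- detect_gait_events(s$recordings$left_lower_leg,
                           s$recordings$right_lower_leg)
  for (leg in c("left", "right")) {
    for (evt in c("mid_swing", "toe_off", "heel_strike")) {
      expect_equal(length(ev[[leg]][[evt]]), length(sim$truth[[leg]][[evt]]))
      expect_lt(max(abs(ev[[leg]][[evt]] - sim$truth[[leg]][[evt]])), 0.0101)
    }
    # ordering invariant per cycle
    expect_true(all(ev[[leg]]$toe_off < ev[[leg]]$mid_swing))
    expect_true(all(ev[[leg]]$mid_swing < ev[[leg]]$heel_strike))
  }
  # scheduled mid-swings 0.5 s apart across alternating legs
  merged <- sort(c(sim$truth$left$mid_swing, sim$truth$right$mid_swing))
  gaps <- diff(merged)
  expect_equal(sort(unique(round(gaps[gaps < 1], 6))), 0.5)
})

test_that("flat or too-short signals raise detection errors", {
  flat <- make_recording("left_lower_leg", n = 1000)
  expect_error(detect_gait_events(flat, flat), "detection error")
})

test_that("turn detection recovers the scheduled window", {
  sim <- simulate_tug(gait_profile(n_steps = 12, turn_duration = 2.0),
                      seed = 6)
  s <- sim$session
  ev <- detect_turn(detect_gait_events(s$recordings$left_lower_leg,
                                       s$recordings$right_lower_leg),
                    s$recordings$low_back)
  expect_lt(abs(unname(ev$turn[2] - ev$turn[1]) - 2.0), 0.021)
  expect_lt(abs(unname(ev$turn[1]) - sim$truth$turn_start), 0.011)
  # monotonicity: longer scheduled turns never shorten the recovered time
  durs <- c(1.6, 2.0, 2.6, 3.2)
  rec <- sapply(durs, function(d) {
    sm <- simulate_tug(gait_profile(n_steps = 12, turn_duration = d), seed = 6)
    e <- detect_turn(detect_gait_events(sm$session$recordings$left_lower_leg,
                                        sm$session$recordings$right_lower_leg),
                     sm$session$recordings$low_back)
    e$turn[2] - e$turn[1]
  })
  expect_true(all(diff(rec) > 0))
})

test_that("continuous walking without a turn raises a turn-detection error", {
  # build a swing train with no gap by stitching two outbound halves
  rate <- 100
  t <- seq(0, 12, by = 1 / rate)
  g <- numeric(length(t))
  for (ms in seq(1, 11, by = 1)) g <- g + 250 * exp(-0.5 * ((t - ms) / 0.05)^2)
  gl <- make_recording("left_lower_leg", n = length(t),
                       gyro = cbind(0, g, 0))
  gr0 <- numeric(length(t))
  for (ms in seq(1.5, 11.5, by = 1)) gr0 <- gr0 + 250 * exp(-0.5 * ((t - ms) / 0.05)^2)
  gr <- make_recording("right_lower_leg", n = length(t),
                       gyro = cbind(0, gr0, 0))
  ev <- detect_gait_events(gl, gr)
  expect_error(detect_turn(ev), "turn-detection error")
})

test_that("gait measures follow the printed definitions", {
  # 10 steps over 2 x 3 m with walk time 7.5 s: step length 0.6, velocity 0.8
  sim <- make_tug_session(seed = 2, n_steps = 10, stride = 1.0)
  s <- sim$session
  ev <- detect_turn(detect_gait_events(s$recordings$left_lower_leg,
                                       s$recordings$right_lower_leg),
                    s$recordings$low_back)
  gm <- gait_measures(ev, s$recordings$low_back, 3)
  expect_equal(gm$tug_n_steps, 10)
  expect_equal(gm$tug_step_length, 0.6)
  expect_lt(abs(gm$tug_step_time - 1.0), 0.011)
  expect_lt(abs(gm$tug_step_time_alt - 0.5), 0.011)
  expect_equal(gm$tug_gait_velocity, sim$truth$gait_velocity,
               tolerance = 0.01)
  expect_lt(abs(gm$tug_walk_time - sim$truth$walk_time), 0.03)
  # turn yaw pulse has a flat top at the profile amplitude
  expect_lt(abs(gm$tug_turn_max_av - 113.78), 0.5)
  expect_error(gait_measures(ev, s$recordings$low_back, -1), "positive")
})

test_that("sts5 segmentation recovers scheduled durations to one sample", {
  st <- simulate_sts5(rep(2.0, 5), seed = 3)
  r <- sts5_measures(st$session$recordings$right_upper_leg)
  expect_equal(nrow(r$transitions), 5)
  expect_lt(max(abs(r$transitions$sit_stand_sit - 2.0)), 0.0101)
  expect_lt(max(abs(r$transitions$sit_stand - st$truth$sit_stand)), 0.0101)
  expect_lt(max(abs(r$transitions$stand_sit - st$truth$stand_sit)), 0.0101)
  expect_lt(abs(r$measures$sts5_duration_sit_stand_sit - 2.0), 0.011)
  # per-cycle structure invariants
  expect_true(all(r$transitions$start < r$transitions$split))
  expect_true(all(r$transitions$split < r$transitions$end))
  expect_equal(r$transitions$sit_stand + r$transitions$stand_sit,
               r$transitions$sit_stand_sit, tolerance = 1e-9)
})

test_that("wrong cycle counts raise cycle-count errors", {
  st <- simulate_sts5(rep(2.0, 5), seed = 3)
  rec <- st$session$recordings$right_upper_leg
  # chop off the last cycle -> 4 pulses
  keep <- rec$time < st$truth$start[5] - 0.3
  rec4 <- sensor_recording("right_upper_leg", acc = rec$acc[keep, ],
                           gyro = rec$gyro[keep, ], sampling_rate = 100)
  expect_error(sts5_measures(rec4), "cycle-count error")
})

test_that("los measures pass through or estimate the reach", {
  lo <- simulate_los(15, seed = 5)
  rec <- lo$session$recordings$low_back
  m <- los_measures(rec, reach_distance = 0.25)
  expect_equal(m$los_reach_distance, 0.25)
  expect_false(m$reach_estimated)
  m2 <- los_measures(rec, reach_distance = NA, height_cm = 155)
  expect_true(m2$reach_estimated)
  expect_lt(abs(m2$los_reach_distance - 1.55 * sin(15 * pi / 180)), 0.002)
  # sway-free trial: ML jerk about zero
  still <- make_recording("low_back", n = 600)
  m3 <- los_measures(still, reach_distance = 0.2)
  expect_equal(m3$los_jerk_gyro_ml, 0, tolerance = 1e-9)
})

test_that("knee ROM is recovered from orientation and from gyro", {
  mf <- simulate_mf(130, "flexion", seed = 4)
  expect_lt(abs(knee_rom(mf$session$recordings$right_upper_leg,
                         mf$session$recordings$right_lower_leg, "flexion") -
                130), 0.5)
  # strip orientation: fall back to drift-corrected gyro integration
  up <- mf$session$recordings$right_upper_leg
  lo <- mf$session$recordings$right_lower_leg
  up$orientation <- NULL
  lo$orientation <- NULL
  expect_lt(abs(knee_rom(up, lo, "flexion") - 130), 2)
  # static trial
  still <- make_recording("right_upper_leg", n = 500)
  still2 <- make_recording("right_lower_leg", n = 500)
  expect_equal(knee_rom(still, still2, "extension"), 0, tolerance = 1e-9)
})

test_that("crt measures implement the information-rate definitions", {
  tr <- data.frame(n_alternatives = c(rep(1, 5), rep(4, 6)),
                   rt_s = c(rep(0.4, 5), rep(0.3, 6)), correct = TRUE)
  m <- crt_measures(app_log("CRT", trials = tr))
  expect_equal(m$crt_simple_reaction_time, 0.4)
  expect_equal(m$crt_information_processing_speed, 2 / 0.3, tolerance = 1e-10)
  tr2 <- data.frame(n_alternatives = c(1, 2), rt_s = c(0.4, 1), correct = TRUE)
  expect_equal(crt_measures(app_log("CRT", trials = tr2))$crt_information_processing_speed, 1)
  tr$correct <- FALSE
  expect_error(crt_measures(app_log("CRT", trials = tr)), "no correct")
})

test_that("fes score is the item sum over the full range", {
  expect_equal(fes_score(app_log("FES", items = rep(1L, 7))), 7)
  expect_equal(fes_score(app_log("FES", items = rep(4L, 7))), 28)
  expect_equal(fes_score(app_log("FES", items = c(1, 1, 2, 1, 1, 2, 2))), 10)
  expect_error(fes_score(app_log("FES", items = rep(1L, 5))), "missing FES item")
})

test_that("a complete battery yields all 155 measures, deterministically", {
  bat <- simulate_battery(1, 1, seed = 99, sway_duration = 12)
  su <- bat$subjects[[1]]
  mv <- extract_all(su$sessions, su$logs, su$record)
  expect_length(mv, 155)
  expect_equal(sum(is.na(mv)), 0)
  expect_setequal(names(mv), measure_catalogue()$measure_id)
  mv2 <- extract_all(su$sessions, su$logs, su$record)
  expect_identical(as.numeric(mv), as.numeric(mv2))
  # partial battery: missing MF flags the ROM measures, others populated
  mv3 <- extract_all(su$sessions[setdiff(names(su$sessions),
                                         c("MF_FLEXION", "MF_EXTENSION"))],
                     su$logs, su$record)
  expect_true(all(is.na(mv3[c("mf_knee_flexion_rom", "mf_knee_extension_rom")])))
  expect_equal(sum(is.na(mv3)), 2)
  expect_setequal(attr(mv3, "missing"),
                  c("mf_knee_flexion_rom", "mf_knee_extension_rom"))
})
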