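#' Gait profile for the timed-up-and-go simulator
#'
#' States the walking the simulator emits: total step count across both
#' feet, stride (same-foot) time mean and SD, swing/trough lobe amplitudes
#' of the shank sagittal angular velocity, the turn duration and low-back
#' yaw-rate amplitude, the one-way walkway distance, and additive sensor
#' noise.  Defaults are the non-faller group values of the study cohort
#' (stride 1.04 s, turn 2.11 s, turn yaw 113.78 deg/s peak, 3 m walkway).
#'
#' @param n_steps Total steps (both feet), >= 6.
#' @param stride_time,stride_time_sd Same-foot cycle time, s.
#' @param swing_peak_amp,swing_peak_sd Mid-swing peak amplitude, deg/s.
#' @param toe_off_trough_amp,heel_strike_trough_amp Negative trough
#'   amplitudes, deg/s.
#' @param turn_duration Turn time, s.
#' @param turn_yaw_rate Flat-top yaw-rate amplitude during the turn, deg/s.
#' @param walkway_distance One-way distance, m.
#' @param noise_sd Additive Gaussian noise on all gyro channels, deg/s.
#' @return A `gait_profile` list.
#' @export
gait_profile <- function(n_steps = 16, stride_time = 1.04,
                         stride_time_sd = 0, swing_peak_amp = 250,
                         swing_peak_sd = 0, toe_off_trough_amp = -60,
                         heel_strike_trough_amp = -80, turn_duration = 2.11,
                         turn_yaw_rate = 113.78, walkway_distance = 3,
                         noise_sd = 0) {
  stopifnot(n_steps >= 6, stride_time > 0, turn_duration > 0,
            swing_peak_amp > max(abs(toe_off_trough_amp),
                                 abs(heel_strike_trough_amp)) * 0)
  if (swing_peak_amp <= max(abs(c(toe_off_trough_amp, heel_strike_trough_amp))))
    stop("swing_peak_amp must exceed the trough amplitudes")
  structure(list(n_steps = as.integer(n_steps), stride_time = stride_time,
                 stride_time_sd = stride_time_sd,
                 swing_peak_amp = swing_peak_amp,
                 swing_peak_sd = swing_peak_sd,
                 toe_off_trough_amp = toe_off_trough_amp,
                 heel_strike_trough_amp = heel_strike_trough_amp,
                 turn_duration = turn_duration, turn_yaw_rate = turn_yaw_rate,
                 walkway_distance = walkway_distance, noise_sd = noise_sd),
            class = "gait_profile")
}

gauss_lobe <- function(t, center, amp, sigma) amp * exp(-0.5 * ((t - center) / sigma)^2)

# flat-top pulse with cosine tapers; max equals amp on the flat section
flat_top_pulse <- function(t, t0, t1, amp, taper) {
  out <- numeric(length(t))
  up <- t >= t0 & t < t0 + taper
  flat <- t >= t0 + taper & t <= t1 - taper
  down <- t > t1 - taper & t <= t1
  out[up] <- amp * 0.5 * (1 - cos(pi * (t[up] - t0) / taper))
  out[flat] <- amp
  out[down] <- amp * 0.5 * (1 - cos(pi * (t1 - t[down]) / taper))
  out
}

#' Simulate a timed-up-and-go session with ground truth
#'
#' Each shank's sagittal angular velocity is a sum of positive Gaussian
#' swing lobes at scheduled mid-swing times (sigma = 5% of the stride
#' time), flanked by negative toe-off and heel-strike lobes, with the legs
#' alternating at a half-stride offset.  The turn is a swing-free window
#' between the outbound and return walking segments whose boundary
#' mid-swings fall exactly on the window edges; the first return swing has
#' a reduced (pivot) amplitude.  The low-back yaw rate is a smooth
#' flat-top pulse of the profile's amplitude during the turn.  Additive
#' Gaussian noise is applied to all gyro channels.
#'
#' @param profile A [gait_profile()].
#' @param seed Integer seed (deterministic output).
#' @param rate Sampling rate, Hz.
#' @return List with `session` (a TUG [session()]) and `truth`
#'   (scheduled event times, turn window, and the implied walk measures).
#' @export
simulate_tug <- function(profile, seed = 1, rate = 100) {
  stopifnot(inherits(profile, "gait_profile"))
  set.seed(seed)
  pr <- profile
  n <- pr$n_steps
  if (pr$turn_duration > n * pr$stride_time)
    stop("spec error: scheduled turn longer than the walking phase of the trial")
  step_int <- pmax(rnorm(n - 1, pr$stride_time / 2, pr$stride_time_sd / 2),
                   0.3 * pr$stride_time)
  n_out <- ceiling(n / 2)
  lead <- 1.5
  ms <- numeric(n)
  ms[1] <- lead
  for (k in 2:n) {
    ms[k] <- ms[k - 1] + step_int[k - 1]
    if (k == n_out + 1) ms[k] <- ms[k - 1] + pr$turn_duration  # cross the turn
  }
  turn_start <- ms[n_out]
  turn_end <- ms[n_out + 1]
  legs <- rep(c("right", "left"), length.out = n)
  amps <- pmax(rnorm(n, pr$swing_peak_amp, pr$swing_peak_sd),
               0.5 * pr$swing_peak_amp)
  amps[n_out + 1] <- 0.8 * amps[n_out + 1]   # cautious pivot step
  delta_to <- 0.25 * pr$stride_time
  delta_hs <- 0.25 * pr$stride_time
  sigma <- 0.05 * pr$stride_time
  toe_off <- ms - delta_to
  heel_strike <- ms + delta_hs

  total <- ms[n] + 1.5
  t <- seq(0, total, by = 1 / rate)
  mk_leg <- function(leg) {
    idx <- which(legs == leg)
    g <- numeric(length(t))
    for (k in idx) {
      g <- g + gauss_lobe(t, ms[k], amps[k], sigma) +
        gauss_lobe(t, toe_off[k], pr$toe_off_trough_amp, 0.6 * sigma) +
        gauss_lobe(t, heel_strike[k], pr$heel_strike_trough_amp, 0.6 * sigma)
    }
    g
  }
  gl <- mk_leg("left")
  gr <- mk_leg("right")
  yaw <- flat_top_pulse(t, turn_start + 0.1 * pr$turn_duration,
                        turn_end - 0.1 * pr$turn_duration,
                        pr$turn_yaw_rate, 0.2 * pr$turn_duration)
  nz <- function() rnorm(length(t), 0, pr$noise_sd)
  walk_osc <- 0.3 * sin(2 * pi * t / pr$stride_time)

  mk_rec <- function(loc, gy, gz = NULL) {
    sensor_recording(loc,
      acc = cbind(0.2 * sin(2 * pi * t / pr$stride_time) + 0.02 * nz(),
                  0.15 * cos(2 * pi * t / pr$stride_time) + 0.02 * nz(),
                  9.81 + 0.3 * sin(4 * pi * t / pr$stride_time) + 0.02 * nz()),
      gyro = cbind(walk_osc + nz(), gy + nz(),
                   (if (is.null(gz)) 0 * t else gz) + nz()),
      sampling_rate = rate)
  }
  recs <- list(
    low_back = mk_rec("low_back", 5 * sin(2 * pi * t / pr$stride_time), yaw),
    left_lower_leg = mk_rec("left_lower_leg", gl),
    right_lower_leg = mk_rec("right_lower_leg", gr))

  sess <- session("sim", "TUG", recs,
                  metadata = list(walkway_distance_m = pr$walkway_distance))
  leg_truth <- function(leg) {
    idx <- which(legs == leg)
    list(mid_swing = ms[idx], toe_off = toe_off[idx],
         heel_strike = heel_strike[idx])
  }
  same_foot <- unlist(lapply(c("left", "right"), function(leg) {
    tt <- ms[legs == leg]
    ints <- diff(tt)
    ints[!(tt[-length(tt)] <= turn_start & tt[-1] >= turn_end)]
  }))
  truth <- structure(list(
    left = leg_truth("left"), right = leg_truth("right"),
    turn_start = turn_start, turn_end = turn_end,
    turn_duration = turn_end - turn_start,
    turn_yaw_rate = pr$turn_yaw_rate,
    n_steps = n,
    step_time = mean(same_foot),
    step_length = 2 * pr$walkway_distance / n,
    walk_time = (heel_strike[n] - toe_off[1]) - (turn_end - turn_start),
    gait_velocity = 2 * pr$walkway_distance /
      ((heel_strike[n] - toe_off[1]) - (turn_end - turn_start))),
    class = "ground_truth")
  list(session = sess, truth = truth)
}

#' Sway profile for the quiet-standing simulator
#'
#' @param rms_acc_ap,rms_acc_ml Target RMS of the mean-removed low-back
#'   acceleration, m/s^2.
#' @param rms_gyro_ap,rms_gyro_ml Target RMS angular velocity, deg/s.
#' @param bandwidth Low-pass bandwidth of the sway processes, Hz (below
#'   Nyquist; postural sway is essentially sub-1 Hz).
#' @param duration Trial length, s (>= 10).
#' @return A `sway_profile` list.
#' @export
sway_profile <- function(rms_acc_ap = 0.012, rms_acc_ml = 0.008,
                         rms_gyro_ap = 1.2, rms_gyro_ml = 1.0,
                         bandwidth = 1, duration = 30) {
  stopifnot(rms_acc_ap >= 0, rms_acc_ml >= 0, rms_gyro_ap >= 0,
            rms_gyro_ml >= 0, bandwidth > 0, duration >= 10)
  structure(list(rms_acc_ap = rms_acc_ap, rms_acc_ml = rms_acc_ml,
                 rms_gyro_ap = rms_gyro_ap, rms_gyro_ml = rms_gyro_ml,
                 bandwidth = bandwidth, duration = duration),
            class = "sway_profile")
}

# band-limited Gaussian process, mean-removed, rescaled to an exact RMS.
# The series is also passed through the pipeline's own 20 Hz low-pass so
# the downstream filter is a no-op and realized RMS survives extraction.
bandlimited_series <- function(n, rate, bandwidth, rms) {
  if (rms == 0) return(numeric(n))
  z <- rnorm(n)
  z <- butterworth_lowpass(z, rate, cutoff = bandwidth, order = 4)
  if (rate / 2 > 20) z <- butterworth_lowpass(z, rate, cutoff = 20, order = 4)
  z <- z - mean(z)
  z * (rms / sqrt(mean(z^2)))
}

#' Simulate a quiet-standing (sensory integration) session
#'
#' Low-back acceleration and angular velocity are band-limited Gaussian
#' processes rescaled post hoc so the realized mean-removed RMS equals the
#' profile value exactly.  The acceleration is interpreted as a tilting
#' gravity vector, and consistent orientation (roll/pitch) channels are
#' emitted, so tilt recovered by [tilt_angles()] matches the generated
#' trajectory.
#'
#' @param profile A [sway_profile()].
#' @param condition One of the four SIT conditions.
#' @param seed Integer seed.
#' @param rate Sampling rate, Hz.
#' @return List with `session` and `truth` (realized RMS, jerk, tilt
#'   ranges and equilibrium scores).
#' @export
simulate_sway <- function(profile, condition = "SIT_EO_FIRM", seed = 1,
                          rate = 100) {
  stopifnot(inherits(profile, "sway_profile"))
  condition <- match.arg(condition, SIT_CONDITIONS)
  if (profile$bandwidth >= rate / 2) stop("bandwidth must be below Nyquist")
  set.seed(seed)
  n <- round(profile$duration * rate) + 1L
  g <- 9.81
  acc_x <- bandlimited_series(n, rate, profile$bandwidth, profile$rms_acc_ap)
  acc_y <- bandlimited_series(n, rate, profile$bandwidth, profile$rms_acc_ml)
  gyro_x <- bandlimited_series(n, rate, profile$bandwidth, profile$rms_gyro_ap)
  gyro_y <- bandlimited_series(n, rate, profile$bandwidth, profile$rms_gyro_ml)
  acc_z <- sqrt(pmax(g^2 - acc_x^2 - acc_y^2, 0))
  pitch <- atan2(acc_x, acc_z) * 180 / pi
  roll <- atan2(acc_y, acc_z) * 180 / pi
  rec <- sensor_recording("low_back",
    acc = cbind(acc_x, acc_y, acc_z),
    gyro = cbind(gyro_x, gyro_y, numeric(n)),
    orientation = cbind(roll, pitch, numeric(n)),
    sampling_rate = rate)
  sess <- session("sim", condition, list(low_back = rec),
                  metadata = list(surface = if (grepl("FOAM", condition))
                    "foam" else "firm",
                    eyes = if (grepl("EO", condition)) "open" else "closed"))
  jerk_of <- function(x) {
    d <- diff(x) * rate
    sqrt(mean((d - mean(d))^2))
  }
  truth <- structure(list(
    rms_acc_ap = profile$rms_acc_ap, rms_acc_ml = profile$rms_acc_ml,
    rms_gyro_ap = profile$rms_gyro_ap, rms_gyro_ml = profile$rms_gyro_ml,
    jerk_acc_ap = jerk_of(acc_x), jerk_acc_ml = jerk_of(acc_y),
    tilt_ap = pitch, tilt_ml = roll,
    es_ap = equilibrium_score(pitch), es_ml = equilibrium_score(roll)),
    class = "ground_truth")
  list(session = sess, truth = truth)
}

# cosine ramp reaching `frac` of full scale exactly at its nominal edge
ramp_up <- function(t, edge, rho, frac = 0.1) {
  delta <- rho * acos(1 - 2 * frac) / pi
  s <- (t - (edge - delta)) / rho
  q <- ifelse(s <= 0, 0, ifelse(s >= 1, 1, 0.5 * (1 - cos(pi * s))))
  q
}

#' Simulate a five-times sit-to-stand session
#'
#' The thigh sagittal angular velocity carries five biphasic pulses: a
#' positive sit-to-stand lobe immediately followed by a negative
#' stand-to-sit lobe.  Lobe ramps are shaped so the 10%-of-peak threshold
#' crossings land exactly on the scheduled transition boundaries, and the
#' positive-to-negative zero crossing lands on the scheduled split.
#'
#' @param transition_durations Either a numeric vector of 5 full-cycle
#'   (sit-stand-sit) durations in s, split between sit-stand and stand-sit
#'   at the cohort ratio 0.97:1.08, or a data.frame with columns
#'   `sit_stand` and `stand_sit` (5 rows).
#' @param seed Integer seed.
#' @param rate Sampling rate, Hz.
#' @param amp_up,amp_down Lobe amplitudes, deg/s.
#' @param rest Pause between cycles, s.
#' @param noise_sd Additive Gaussian gyro noise, deg/s.
#' @return List with `session` and `truth` (scheduled boundaries and
#'   durations).
#' @export
simulate_sts5 <- function(transition_durations, seed = 1, rate = 100,
                          amp_up = 120, amp_down = -100, rest = 0.8,
                          noise_sd = 0) {
  if (is.data.frame(transition_durations)) {
    stopifnot(all(c("sit_stand", "stand_sit") %in% names(transition_durations)))
    d_ss <- transition_durations$sit_stand
    d_st <- transition_durations$stand_sit
  } else {
    ratio <- 0.97 / (0.97 + 1.08)
    d_ss <- transition_durations * ratio
    d_st <- transition_durations * (1 - ratio)
  }
  if (length(d_ss) != 5L)
    stop("spec error: exactly 5 cycles required")
  if (any(d_ss <= 0) || any(d_st <= 0))
    stop("spec error: transition durations must be positive")
  set.seed(seed)
  rho <- 0.12   # ramp length, s
  t0 <- numeric(5); tm <- numeric(5); t1 <- numeric(5)
  cur <- 1.5
  for (k in 1:5) {
    t0[k] <- cur
    tm[k] <- t0[k] + d_ss[k]
    t1[k] <- tm[k] + d_st[k]
    cur <- t1[k] + rest
  }
  if (any(diff(t0) <= 0)) stop("spec error: scheduled cycles overlap")
  total <- t1[5] + 1.5
  t <- seq(0, total, by = 1 / rate)
  y <- numeric(length(t))
  for (k in 1:5) {
    # positive lobe: rises at t0 (10% crossing there), falls to 0 at the split
    pos <- amp_up * ramp_up(t, t0[k], rho) *
      ifelse(t < tm[k], 0.5 * (1 - cos(pi * pmin(pmax((tm[k] - t) / (rho), 0), 1))), 0)
    neg <- amp_down * ramp_up(-t, -t1[k], rho) *
      ifelse(t > tm[k], 0.5 * (1 - cos(pi * pmin(pmax((t - tm[k]) / (rho), 0), 1))), 0)
    y <- y + pos + neg
  }
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  rec <- sensor_recording("right_upper_leg",
    acc = cbind(0.05 * y / max(abs(y)), numeric(length(t)), rep(9.81, length(t))),
    gyro = cbind(numeric(length(t)), y, numeric(length(t))),
    sampling_rate = rate)
  sess <- session("sim", "STS5", list(right_upper_leg = rec))
  truth <- structure(list(start = t0, split = tm, end = t1,
                          sit_stand = d_ss, stand_sit = d_st,
                          sit_stand_sit = d_ss + d_st),
                     class = "ground_truth")
  list(session = sess, truth = truth)
}

#' Simulate a knee motor-function session
#'
#' The lower-leg pitch sweeps smoothly from 0 to `rom_deg` and back while
#' the upper leg stays still; both recordings carry consistent orientation
#' and sagittal angular-velocity channels.
#'
#' @param rom_deg Knee range of motion, deg.
#' @param task `"flexion"` or `"extension"`.
#' @param seed Integer seed.
#' @param duration Trial length, s.
#' @param rate Sampling rate, Hz.
#' @param noise_sd Orientation noise, deg.
#' @return List with `session` and `truth` (`rom`).
#' @export
simulate_mf <- function(rom_deg, task = c("flexion", "extension"), seed = 1,
                        duration = 6, rate = 100, noise_sd = 0) {
  task <- match.arg(task)
  set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  sweep <- rom_deg * 0.5 * (1 - cos(2 * pi * t / duration))
  if (noise_sd > 0) sweep <- sweep + rnorm(length(t), 0, noise_sd)
  gy <- derivative(sweep, rate)
  n <- length(t)
  zero <- numeric(n)
  lower <- sensor_recording("right_lower_leg",
    acc = cbind(zero, zero, rep(9.81, n)), gyro = cbind(zero, gy, zero),
    orientation = cbind(zero, sweep, zero), sampling_rate = rate)
  upper <- sensor_recording("right_upper_leg",
    acc = cbind(zero, zero, rep(9.81, n)), gyro = cbind(zero, zero, zero),
    orientation = cbind(zero, zero, zero), sampling_rate = rate)
  sess <- session("sim", if (task == "flexion") "MF_FLEXION" else "MF_EXTENSION",
                  list(right_upper_leg = upper, right_lower_leg = lower))
  list(session = sess,
       truth = structure(list(rom = max(sweep) - min(sweep)),
                         class = "ground_truth"))
}

#' Simulate a limits-of-stability (forward reach) session
#'
#' The trunk pitches forward to `peak_pitch_deg` and returns over the
#' trial; orientation channels are emitted so the reach estimate
#' `height * sin(peak pitch)` is recoverable.
#'
#' @param peak_pitch_deg Peak forward trunk pitch, deg.
#' @param seed Integer seed.
#' @param duration Trial length, s.
#' @param rate Sampling rate, Hz.
#' @param noise_sd Gyro noise, deg/s.
#' @return List with `session` and `truth` (`peak_pitch`).
#' @export
simulate_los <- function(peak_pitch_deg = 12, seed = 1, duration = 5,
                         rate = 100, noise_sd = 0) {
  set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  pitch <- peak_pitch_deg * 0.5 * (1 - cos(2 * pi * t / duration))
  gy <- derivative(pitch, rate)
  n <- length(t)
  zero <- numeric(n)
  g <- 9.81
  acc_x <- g * sin(pitch * pi / 180)
  rec <- sensor_recording("low_back",
    acc = cbind(acc_x, zero, sqrt(g^2 - acc_x^2)),
    gyro = cbind(0.3 * sin(2 * pi * t / duration) + rnorm(n, 0, noise_sd),
                 gy + rnorm(n, 0, noise_sd),
                 0.2 * sin(2 * pi * t / duration) + rnorm(n, 0, noise_sd)),
    orientation = cbind(zero, pitch, zero), sampling_rate = rate)
  sess <- session("sim", "LOS", list(low_back = rec))
  list(session = sess,
       truth = structure(list(peak_pitch = max(pitch)), class = "ground_truth"))
}

#' Simulate a choice-reaction-test log
#'
#' @param ips Target information processing speed, bit/s.
#' @param srt Target simple reaction time, s.
#' @param seed Integer seed.
#' @param n_simple,n_choice Trial counts.
#' @param n_alternatives Alternatives in the choice block.
#' @return An [app_log()] of kind CRT.
#' @export
simulate_crt_log <- function(ips = 7, srt = 0.44, seed = 1, n_simple = 10,
                             n_choice = 20, n_alternatives = 4) {
  set.seed(seed)
  rt_choice <- pmax(rnorm(n_choice, log2(n_alternatives) / ips, 0.03), 0.05)
  rt_simple <- pmax(rnorm(n_simple, srt, 0.04), 0.05)
  trials <- data.frame(
    trial = seq_len(n_simple + n_choice),
    n_alternatives = c(rep(1L, n_simple), rep(n_alternatives, n_choice)),
    rt_s = c(rt_simple, rt_choice),
    correct = TRUE)
  app_log("CRT", trials = trials)
}

#' Simulate a falls-efficacy-scale log
#'
#' Distributes a target total score over 7 items in 1-4.
#'
#' @param target_score Desired total (clamped to the 7-28 scale range).
#' @param seed Integer seed.
#' @return An [app_log()] of kind FES.
#' @export
simulate_fes_log <- function(target_score = 10, seed = 1) {
  set.seed(seed)
  target <- round(min(28, max(7, target_score)))
  items <- rep(1L, 7L)
  while (sum(items) < target) {
    i <- sample(which(items < 4L), 1L)
    items[i] <- items[i] + 1L
  }
  app_log("FES", items = items)
}

#' Cohort specification for feature-level simulation
#'
#' @param n_nonfaller,n_faller Group sizes (defaults 114 and 82, the study
#'   cohort).
#' @param stats Per-measure per-group table as from
#'   [default_measure_stats()]; columns `measure_id`, `nf_mean`, `nf_sd`,
#'   `f_mean`, `f_sd`.
#' @param corr Optional between-measure correlation matrix (positive
#'   semi-definite, dimensions matching `nrow(stats)`).
#' @param seed Master integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_nonfaller = 114, n_faller = 82,
                        stats = default_measure_stats(), corr = NULL,
                        seed = 1) {
  stopifnot(n_nonfaller >= 2, n_faller >= 2)
  need <- c("measure_id", "nf_mean", "nf_sd", "f_mean", "f_sd")
  if (!all(need %in% names(stats))) stop("stats table missing columns")
  unknown <- setdiff(stats$measure_id, measure_catalogue()$measure_id)
  if (length(unknown))
    stop(sprintf("validation error: measure(s) not in catalogue: %s",
                 paste(head(unknown, 5), collapse = ", ")))
  if (any(stats$nf_sd <= 0) || any(stats$f_sd <= 0))
    stop("validation error: SDs must be positive")
  if (!is.null(corr)) {
    stopifnot(nrow(corr) == nrow(stats), ncol(corr) == nrow(stats))
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("validation error: correlation matrix not positive semi-definite")
  }
  structure(list(n_nonfaller = n_nonfaller, n_faller = n_faller,
                 stats = stats, corr = corr, seed = seed),
            class = "cohort_spec")
}

# reproducible per-subject substream of a master seed
subject_seed <- function(master, i) (as.numeric(master) * 1009 + i * 7907) %% 2147483647

#' Simulate a feature-level faller/non-faller cohort
#'
#' Draws each subject's 155-measure vector from the per-group normal (or,
#' with a correlation matrix, multivariate normal) distributions of the
#' spec.  Each subject uses a seed derived from the master seed by a
#' counter scheme, so individual subjects are reproducible.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame: `subject_id`, `fall_status`, then one column per
#'   measure.
#' @export
simulate_cohort_features <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  st <- spec$stats
  p <- nrow(st)
  L <- if (!is.null(spec$corr)) {
    ev <- eigen(spec$corr, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  } else NULL
  draw <- function(i, mu, sdv) {
    set.seed(subject_seed(spec$seed, i))
    z <- rnorm(p)
    if (!is.null(L)) z <- as.numeric(L %*% z)
    mu + sdv * z
  }
  n <- spec$n_nonfaller + spec$n_faller
  status <- c(rep("non_faller", spec$n_nonfaller), rep("faller", spec$n_faller))
  rows <- matrix(NA_real_, n, p, dimnames = list(NULL, st$measure_id))
  for (i in seq_len(n)) {
    if (status[i] == "non_faller") rows[i, ] <- draw(i, st$nf_mean, st$nf_sd)
    else rows[i, ] <- draw(i, st$f_mean, st$f_sd)
  }
  out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    fall_status = status, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(rows))
}

#' Simulate cohort demographics
#'
#' Ages, heights and weights from the per-group normal distributions of
#' the study's demographics table; fall histories consistent with the
#' faller labelling rule.
#'
#' @param n_nonfaller,n_faller Group sizes.
#' @param seed Integer seed.
#' @return data.frame in the cohort-table format of [read_cohort()], with
#'   derived `bmi` and `fall_status`.
#' @export
simulate_demographics <- function(n_nonfaller = 114, n_faller = 82, seed = 1) {
  set.seed(seed)
  n <- n_nonfaller + n_faller
  status <- c(rep("non_faller", n_nonfaller), rep("faller", n_faller))
  nf <- status == "non_faller"
  age <- ifelse(nf, rnorm(n, 72.02, 4.17), rnorm(n, 72.35, 4.74))
  height <- ifelse(nf, rnorm(n, 154.83, 5.01), rnorm(n, 154.41, 5.31))
  weight <- ifelse(nf, rnorm(n, 58.01, 6.93), rnorm(n, 61.01, 8.05))
  n_falls <- ifelse(nf, rbinom(n, 1, 0.3), 2 + rbinom(n, 2, 0.3))
  injurious <- ifelse(nf, 0L, rbinom(n, 1, 0.18))
  one_inj <- !nf & runif(n) < 0.2        # fallers by the injurious-fall route
  n_falls[one_inj] <- 1L
  injurious[one_inj] <- 1L
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   age = round(pmax(age, 65), 1),
                   height_cm = round(height, 1),
                   weight_kg = round(pmax(weight, 35), 1),
                   n_falls_past_year = n_falls,
                   injurious_fall = injurious, stringsAsFactors = FALSE)
  df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  df$fall_status <- classify_fall_status(df$n_falls_past_year,
                                         df$injurious_fall == 1)
  stopifnot(df$fall_status == status)
  df
}

#' Simulate a complete signal-level battery for a cohort
#'
#' For each subject, draws subtest parameters from the group-conditional
#' distributions of the published cohort (stride and turn times, transition
#' durations, sway magnitudes, knee ROM, processing speed, FES score) and
#' generates all sensor sessions and app logs.  This is the input of the
#' end-to-end demo pipeline.
#'
#' @param n_nonfaller,n_faller Group sizes.
#' @param seed Master seed.
#' @param sway_duration SIT trial length, s (default 30).
#' @return List with `subjects` (per subject: `record`, `sessions`, `logs`,
#'   `truth`) and `demographics`.
#' @export
simulate_battery <- function(n_nonfaller = 10, n_faller = 10, seed = 1,
                             sway_duration = 30) {
  demo <- simulate_demographics(n_nonfaller, n_faller, seed)
  subjects <- vector("list", nrow(demo))
  for (i in seq_len(nrow(demo))) {
    s <- subject_seed(seed, i)
    set.seed(s)
    faller <- demo$fall_status[i] == "faller"
    grp <- function(nf, f) if (faller) f else nf
    stride <- max(rnorm(1, grp(1.04, 1.08), grp(0.08, 0.13)), 0.7)
    turn_dur <- max(rnorm(1, grp(2.11, 2.43), grp(0.43, 0.61)), 1.2)
    turn_yaw <- max(rnorm(1, grp(113.78, 104.93), grp(10.89, 16.31)), 60)
    step_len <- max(rnorm(1, grp(0.39, 0.36), 0.04), 0.25)
    n_steps <- max(8L, round(6 / step_len))
    d_ss <- pmax(rnorm(5, grp(0.97, 1.17), grp(0.19, 0.39) / 2), 0.5)
    d_st <- pmax(rnorm(5, grp(1.08, 1.32), grp(0.26, 0.55) / 2), 0.5)
    rom_flex <- max(rnorm(1, grp(131.73, 124.95), grp(13.38, 12.99)), 80)
    rom_ext <- max(rnorm(1, grp(4.29, 3.69), grp(1.55, 1.82)), 1)
    ips <- max(rnorm(1, grp(7.09, 5.82), grp(1.28, 1.27)), 2)
    fes <- round(max(rnorm(1, grp(9.73, 14.96), grp(2.98, 4.92)), 7))
    sway_scale <- grp(1, 1.35) * exp(rnorm(1, 0, 0.25))

    sims <- list()
    for (k in seq_along(SIT_CONDITIONS)) {
      cond <- SIT_CONDITIONS[k]
      hard <- grepl("FOAM", cond)
      pr <- sway_profile(
        rms_acc_ap = 0.01 * (1 + hard) * sway_scale,
        rms_acc_ml = 0.006 * (1 + hard) * sway_scale,
        rms_gyro_ap = 0.9 * (1 + 0.5 * hard) * sway_scale,
        rms_gyro_ml = 0.8 * (1 + 0.5 * hard) * sway_scale,
        duration = sway_duration)
      sims[[cond]] <- simulate_sway(pr, cond, seed = s + k)$session
    }
    sims$LOS <- simulate_los(peak_pitch_deg = grp(13, 11) + rnorm(1, 0, 1.5),
                             seed = s + 11)$session
    sims$STS5 <- simulate_sts5(data.frame(sit_stand = d_ss, stand_sit = d_st),
                               seed = s + 12)$session
    sims$TUG <- simulate_tug(gait_profile(
      n_steps = n_steps, stride_time = stride, stride_time_sd = 0.03,
      swing_peak_amp = 250, swing_peak_sd = 12, turn_duration = turn_dur,
      turn_yaw_rate = turn_yaw, noise_sd = 5), seed = s + 13)$session
    sims$MF_FLEXION <- simulate_mf(rom_flex, "flexion", seed = s + 14)$session
    sims$MF_EXTENSION <- simulate_mf(rom_ext, "extension", seed = s + 15)$session
    for (nm in names(sims)) sims[[nm]]$subject_id <- demo$subject_id[i]

    logs <- list(CRT = simulate_crt_log(ips = ips, seed = s + 16),
                 FES = simulate_fes_log(fes, seed = s + 17))
    rec <- subject_record(demo$subject_id[i], demo$age[i], demo$height_cm[i],
                          demo$weight_kg[i], demo$n_falls_past_year[i],
                          demo$injurious_fall[i] == 1)
    subjects[[i]] <- list(record = rec, sessions = sims, logs = logs)
  }
  list(subjects = subjects, demographics = demo)
}
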