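#' Root-mean-square amplitude (sway convention)
#'
#' RMS of the mean-removed series, the convention used for postural-sway
#' acceleration and angular-velocity magnitudes.
#'
#' @param x Non-empty numeric series.
#' @return Scalar in the units of `x`.
#' @export
rms_amplitude <- function(x) {
  if (!length(x)) stop("rms of empty series")
  sqrt(mean((x - mean(x))^2))
}

#' Movement-smoothness jerk measure
#'
#' RMS (mean-removed) of the time derivative of a series: for acceleration
#' this is jerk proper (units/s^3); applied to angular velocity it is the
#' RMS angular acceleration, the study's "jerk in angular velocity".
#'
#' @param x Numeric series (length >= 3).
#' @param rate Sampling rate in Hz.
#' @param mean_removed Subtract the mean derivative before taking the RMS
#'   (default TRUE, the sway convention; a pure ramp then scores 0).
#' @return Scalar in units of `x` per second.
#' @export
jerk_measure <- function(x, rate, mean_removed = TRUE) {
  d <- derivative(x, rate)
  if (mean_removed) rms_amplitude(d) else sqrt(mean(d^2))
}

#' Spectral summary of a sway series
#'
#' Welch-averaged periodogram (Hann window, 50% overlap) of the
#' mean-removed series, summarized as the median frequency (splits
#' cumulative power in half), the spectral centroid (power-weighted mean
#' frequency) and the total power (integral of the density).
#'
#' @param x Numeric series, length >= 256.
#' @param rate Sampling rate in Hz.
#' @param nperseg Segment length (default 256).
#' @return List with `median_freq`, `centroid_freq` (Hz), `total_power`
#'   (units^2) and the `freq`/`psd` vectors.
#' @export
frequency_measures <- function(x, rate, nperseg = 256) {
  n <- length(x)
  if (n < 256) stop("length error: frequency_measures needs >= 256 samples")
  nperseg <- min(nperseg, n)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))  # Hann
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nf <- floor(nperseg / 2) + 1L
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / (rate * sum(w^2))
    half <- P[seq_len(nf)]
    # fold the negative frequencies into the one-sided density
    if (nperseg %% 2 == 0) half[2:(nf - 1)] <- 2 * half[2:(nf - 1)]
    else half[2:nf] <- 2 * half[2:nf]
    psd <- psd + half
  }
  psd <- psd / length(starts)
  freq <- (seq_len(nf) - 1L) * rate / nperseg
  total <- sum(psd) * rate / nperseg
  cum <- cumsum(psd)
  med_i <- which(cum >= cum[nf] / 2)[1]
  list(median_freq = freq[med_i],
       centroid_freq = sum(freq * psd) / sum(psd),
       total_power = total, freq = freq, psd = psd)
}

#' Equilibrium score
#'
#' 0-100 postural-stability score: `100 * (1 - sway_range / theta_limit)`
#' clamped to the 0-100 range, where sway range is the peak-to-peak excursion of
#' the tilt-angle series and `theta_limit` is the theoretical limit of
#' stability (default 12.5 deg, the standard posturography convention).
#'
#' @param theta Tilt-angle series in degrees.
#' @param theta_limit Stability limit in degrees (> 0).
#' @return Score between 0 and 100.
#' @export
equilibrium_score <- function(theta, theta_limit = 12.5) {
  if (!length(theta)) stop("empty tilt series")
  if (theta_limit <= 0) stop("theta_limit must be positive")
  min(100, max(0, 100 * (1 - (max(theta) - min(theta)) / theta_limit)))
}

#' Sensory-system scores from condition equilibrium scores
#'
#' Ratio convention relating the four quiet-standing conditions to the
#' three sensory systems: somatosensory = 100 * ES(eyes closed, firm) /
#' ES(eyes open, firm); visual = 100 * ES(eyes open, foam) / ES(eyes open,
#' firm); vestibular = 100 * ES(eyes closed, foam) / ES(eyes open, firm).
#' Scores are capped at 100.  If the reference ES is 0 the scores are
#' undefined and returned as NA.
#'
#' @param es Named numeric vector with elements `eo_firm`, `ec_firm`,
#'   `eo_foam`, `ec_foam` (one direction at a time).
#' @return Named vector `c(som=, vis=, vest=)`.
#' @export
sensory_system_scores <- function(es) {
  need <- c("eo_firm", "ec_firm", "eo_foam", "ec_foam")
  if (!all(need %in% names(es)))
    stop(sprintf("missing condition ES: %s",
                 paste(setdiff(need, names(es)), collapse = ", ")))
  ref <- es[["eo_firm"]]
  if (!is.finite(ref) || ref == 0)
    return(c(som = NA_real_, vis = NA_real_, vest = NA_real_))
  cap <- function(v) min(100, v)
  c(som = cap(100 * es[["ec_firm"]] / ref),
    vis = cap(100 * es[["eo_foam"]] / ref),
    vest = cap(100 * es[["ec_foam"]] / ref))
}

# local maxima/minima of a series (strict on the left, non-strict right)
local_extrema <- function(x, maxima = TRUE) {
  if (!maxima) x <- -x
  n <- length(x)
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# greedy peak pruning: keep highest peaks subject to a minimum separation
enforce_separation <- function(idx, height, min_sep) {
  keep <- logical(length(idx))
  for (o in order(height, decreasing = TRUE)) {
    if (!any(keep & abs(idx - idx[o]) < min_sep)) keep[o] <- TRUE
  }
  sort(idx[keep])
}

detect_leg_events <- function(gyro_y, rate, amp_frac = 0.4, amp_floor = 50,
                              sep_frac = 0.4) {
  g <- gyro_y
  thr <- max(amp_frac * max(abs(g)), amp_floor)
  cand <- local_extrema(g, maxima = TRUE)
  cand <- cand[g[cand] >= thr]
  if (length(cand) < 2)
    stop(sprintf(paste0("detection error: %d mid-swing candidate(s) above ",
                        "threshold %.1f deg/s (need >= 2)"),
         length(cand), thr))
  # two-pass separation rule: rough pass, then 0.4 x median inter-peak gap
  cand1 <- enforce_separation(cand, g[cand], round(0.3 * rate))
  med_gap <- median(diff(cand1))
  peaks <- enforce_separation(cand, g[cand], max(2, round(sep_frac * med_gap)))
  # troughs: deepest point in the half-cycle windows flanking each
  # mid-swing (robust to noise dimples near the peak)
  half <- round(0.5 * median(diff(peaks)))
  n <- length(g)
  toe_off <- heel_strike <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    lo <- if (k > 1) max(peaks[k - 1] + 1L, peaks[k] - half) else
      max(1L, peaks[k] - half)
    hi <- if (k < length(peaks)) min(peaks[k + 1] - 1L, peaks[k] + half) else
      min(n, peaks[k] + half)
    wb <- lo:(peaks[k] - 1L)
    wa <- (peaks[k] + 1L):hi
    toe_off[k] <- wb[which.min(g[wb])]
    heel_strike[k] <- wa[which.min(g[wa])]
  }
  list(mid_swing = peaks, toe_off = toe_off,
       heel_strike = heel_strike, amplitude = g[peaks],
       threshold = thr)
}

#' Detect gait events from shank angular velocity
#'
#' Mid-swings are the high peaks of the (low-pass-filtered) sagittal shank
#' angular velocity in each gait cycle; the troughs immediately left and
#' right of each mid-swing are taken as toe-off and heel-strike.  The peak
#' threshold is adaptive: `max(amp_frac * max|gyro_y|, amp_floor)` per leg,
#' with a minimum peak separation of `sep_frac` times the median inter-peak
#' interval.
#'
#' @param left_shank,right_shank [sensor_recording()]s at the lower legs
#'   (or raw numeric gyro-y series).
#' @param rate Sampling rate (taken from the recordings when omitted).
#' @param params List overriding `amp_frac` (0.4), `amp_floor` (50 deg/s),
#'   `sep_frac` (0.4), `cutoff` (20 Hz filter).
#' @return A `gait_events` object: per-leg `mid_swing`, `toe_off`,
#'   `heel_strike` times (s) and peak amplitudes; `turn` is NULL until
#'   [detect_turn()] fills it.
#' @export
detect_gait_events <- function(left_shank, right_shank, rate = NULL,
                               params = list()) {
  p <- modifyList(list(amp_frac = 0.4, amp_floor = 50, sep_frac = 0.4,
                       cutoff = 20), params)
  get_gy <- function(rec) {
    if (inherits(rec, "sensor_recording")) {
      if (is.null(rate)) rate <<- rec$sampling_rate
      butterworth_lowpass(rec$gyro[, "y"], rec$sampling_rate, p$cutoff)
    } else as.numeric(rec)
  }
  gl <- get_gy(left_shank)
  gr <- get_gy(right_shank)
  if (is.null(rate)) stop("rate must be supplied with raw series")
  legs <- list(left = detect_leg_events(gl, rate, p$amp_frac, p$amp_floor,
                                        p$sep_frac),
               right = detect_leg_events(gr, rate, p$amp_frac, p$amp_floor,
                                         p$sep_frac))
  out <- lapply(legs, function(ev) {
    lapply(ev[c("mid_swing", "toe_off", "heel_strike")],
           function(i) (i - 1) / rate)
  })
  out$left$amplitude <- legs$left$amplitude
  out$right$amplitude <- legs$right$amplitude
  for (leg in c("left", "right")) {
    e <- out[[leg]]
    bad <- !(e$toe_off < e$mid_swing & e$mid_swing < e$heel_strike)
    if (any(bad)) stop("detection error: event ordering violated")
  }
  structure(list(left = out$left, right = out$right, rate = rate,
                 turn = NULL), class = "gait_events")
}

#' Detect the turning phase of a timed-up-and-go trial
#'
#' During the 180-degree turn neither leg produces a threshold-passing
#' mid-swing, so the turn appears as a gap in the merged mid-swing
#' sequence.  The turn start is the last mid-swing before the gap; the turn
#' end is the first post-gap mid-swing whose peak amplitude is lower than
#' the contralateral leg's following peak (the cautious pivot step).  The
#' duration between these two points is the turning time.
#'
#' @param events A `gait_events` object from [detect_gait_events()].
#' @param low_back Optional low-back [sensor_recording()]; stored yaw-rate
#'   excerpt is attached for turn angular-velocity measures.
#' @param rate Sampling rate (defaults to `events$rate`).
#' @param params List overriding `gap_factor` (1.8): a merged inter-swing
#'   interval larger than `gap_factor` times the median counts as the turn.
#' @return `events` with `turn = c(turn_start, turn_end)` in seconds.
#' @export
detect_turn <- function(events, low_back = NULL, rate = NULL, params = list()) {
  stopifnot(inherits(events, "gait_events"))
  p <- modifyList(list(gap_factor = 1.8), params)
  if (is.null(rate)) rate <- events$rate
  sw <- rbind(
    data.frame(t = events$left$mid_swing, amp = events$left$amplitude,
               leg = "left", stringsAsFactors = FALSE),
    data.frame(t = events$right$mid_swing, amp = events$right$amplitude,
               leg = "right", stringsAsFactors = FALSE))
  sw <- sw[order(sw$t), ]
  if (nrow(sw) < 4) stop("turn-detection error: too few mid-swings")
  gaps <- diff(sw$t)
  med <- median(gaps)
  big <- which(gaps > p$gap_factor * med)
  if (!length(big))
    stop("turn-detection error: no gap in the mid-swing sequence")
  g <- big[which.max(gaps[big])]
  turn_start <- sw$t[g]
  # end: first post-gap swing with amplitude below the contralateral next
  turn_end <- NA_real_
  for (k in (g + 1):nrow(sw)) {
    contra <- which(sw$t > sw$t[k] & sw$leg != sw$leg[k])
    if (length(contra) && sw$amp[k] < sw$amp[contra[1]]) {
      turn_end <- sw$t[k]
      break
    }
  }
  if (is.na(turn_end)) turn_end <- sw$t[g + 1]
  events$turn <- c(turn_start = turn_start, turn_end = turn_end)
  events
}

#' Walking and turning measures of a timed-up-and-go trial
#'
#' Step time is the mean interval between consecutive toe-offs of the same
#' foot (the published definition; conventionally a stride time).  Because
#' that definition is internally inconsistent with counting steps across
#' both feet, the alternating-foot step time is also emitted as
#' `step_time_alt`.  Steps are mid-swings outside the turn; average step
#' length is total distance (out + back) divided by the number of steps;
#' walking time is last heel-strike minus first toe-off excluding the
#' turning time; gait velocity is total distance over walking time.
#' Turn angular-velocity measures are computed from the low-back yaw rate
#' inside the turn window (RMS/mean/max of the raw, not mean-removed,
#' signal, since the turn is a one-sided pulse).
#'
#' @param events A `gait_events` object with the turn detected.
#' @param low_back Low-back [sensor_recording()].
#' @param walkway_distance One-way walkway length in m (default 3).
#' @return Named list of TUG measures (`tug_*` ids of the catalogue).
#' @export
gait_measures <- function(events, low_back, walkway_distance = 3) {
  stopifnot(inherits(events, "gait_events"))
  if (walkway_distance <= 0) stop("walkway_distance must be positive")
  if (is.null(events$turn))
    events <- detect_turn(events, low_back)
  ts <- events$turn[["turn_start"]]
  te <- events$turn[["turn_end"]]
  turn_time <- te - ts

  all_ms <- sort(c(events$left$mid_swing, events$right$mid_swing))
  n_steps <- sum(all_ms <= ts | all_ms >= te)
  if (n_steps == 0) stop("zero steps detected")

  same_foot_ints <- function(tt) {
    ints <- diff(tt)
    span <- tt[-length(tt)] < ts & tt[-1] > ts   # pairs straddling the turn
    ints[!span]
  }
  st_l <- same_foot_ints(events$left$toe_off)
  st_r <- same_foot_ints(events$right$toe_off)
  step_time <- mean(c(st_l, st_r))
  step_time_sd <- sd(c(st_l, st_r))
  alt <- same_foot_ints(sort(c(events$left$toe_off, events$right$toe_off)))
  step_time_alt <- mean(alt)

  first_to <- min(events$left$toe_off, events$right$toe_off)
  last_hs <- max(events$left$heel_strike, events$right$heel_strike)
  total_time <- last_hs - first_to
  walk_time <- total_time - turn_time
  dist <- 2 * walkway_distance

  out <- list(
    tug_gait_velocity = dist / walk_time,
    tug_step_time = step_time,
    tug_step_time_alt = step_time_alt,
    tug_step_time_sd = step_time_sd,
    tug_step_length = dist / n_steps,
    tug_n_steps = n_steps,
    tug_walk_time = walk_time,
    tug_total_time = total_time,
    tug_turn_time = turn_time)

  if (!is.null(low_back)) {
    rate <- low_back$sampling_rate
    lb <- filter_recording(low_back)
    t <- lb$time
    walk_idx <- which(t <= ts | t >= te)
    turn_idx <- which(t >= ts & t <= te)
    for (dir in c(ap = "x", ml = "y", v = "z")) {
      nm <- names(which(c(ap = "x", ml = "y", v = "z") == dir))
      out[[paste0("tug_rms_acc_", nm)]] <- rms_amplitude(lb$acc[walk_idx, dir])
      out[[paste0("tug_rms_gyro_", nm)]] <- rms_amplitude(lb$gyro[walk_idx, dir])
      out[[paste0("tug_jerk_acc_", nm)]] <- jerk_measure(lb$acc[walk_idx, dir], rate)
    }
    yaw <- lb$gyro[turn_idx, "z"]
    out$tug_turn_rms_av <- sqrt(mean(yaw^2))
    out$tug_turn_max_av <- max(abs(yaw))
    out$tug_turn_mean_av <- mean(abs(yaw))
  }
  out
}

#' Segment and score a five-times sit-to-stand trial
#'
#' The thigh sagittal angular velocity shows one biphasic pulse per cycle
#' (positive sit-to-stand lobe immediately followed by a negative
#' stand-to-sit lobe).  Cycles are segmented where the rectified filtered
#' signal exceeds `threshold_frac` of its maximum (gaps shorter than
#' `min_gap` s are closed, bridging the zero crossing between the lobes);
#' exactly 5 cycles are required.  Within a cycle the positive-to-negative
#' zero crossing splits sit-to-stand from stand-to-sit.  Per transition the
#' duration, mean and max rectified angular velocity and the jerk
#' (RMS angular acceleration) are emitted, averaged over the 5 cycles.
#'
#' @param upper_leg Upper-leg [sensor_recording()].
#' @param params List overriding `threshold_frac` (0.1), `min_gap` (0.25 s),
#'   `cutoff` (20 Hz).
#' @return List with `transitions` (data.frame, one row per cycle:
#'   start/split/end times and the three durations) and `measures` (named
#'   list of the `sts5_*` catalogue measures).
#' @export
sts5_measures <- function(upper_leg, params = list()) {
  p <- modifyList(list(threshold_frac = 0.1, min_gap = 0.25, cutoff = 20),
                  params)
  rate <- upper_leg$sampling_rate
  y <- butterworth_lowpass(upper_leg$gyro[, "y"], rate, p$cutoff)
  env <- abs(y)
  thr <- p$threshold_frac * max(env)
  active <- env > thr
  # close short gaps (the zero crossing inside a cycle)
  r <- rle(active)
  gap <- !r$values & r$lengths < p$min_gap * rate
  first <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  inner <- gap & seq_along(gap) > 1 & seq_along(gap) < length(gap)
  r$values[inner] <- TRUE
  active <- inverse.rle(r)
  r2 <- rle(active)
  ends <- cumsum(r2$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  regions <- cbind(starts[r2$values], ends[r2$values])
  if (nrow(regions) != 5L)
    stop(sprintf("cycle-count error: detected %d sit-to-stand cycle(s), expected 5",
                 nrow(regions)))
  t_of <- function(i) (i - 1) / rate
  # sub-sample crossing of |y| = level between samples i (below) and i+1
  cross_t <- function(i, level) {
    if (i < 1) return(t_of(1))
    a <- abs(y[i]); b <- abs(y[i + 1])
    t_of(i) + (level - a) / (b - a) / rate
  }
  cyc <- vector("list", 5L)
  for (k in 1:5) {
    i0 <- regions[k, 1]; i1 <- regions[k, 2]
    seg <- y[i0:i1]
    pk_pos <- i0 + which.max(seg) - 1L
    pk_neg <- i0 + which.min(seg) - 1L
    if (y[pk_pos] <= 0 || y[pk_neg] >= 0 || pk_neg <= pk_pos)
      stop("cycle-count error: no biphasic lobe pair in a detected cycle")
    # refine boundaries against the cycle's own lobe peaks (10% of peak)
    lev0 <- p$threshold_frac * y[pk_pos]
    i <- pk_pos
    while (i > 1 && abs(y[i - 1]) >= lev0) i <- i - 1L
    tt0 <- cross_t(i - 1L, lev0)
    lev1 <- p$threshold_frac * abs(y[pk_neg])
    j <- pk_neg
    while (j < length(y) && abs(y[j + 1]) >= lev1) j <- j + 1L
    ttm1 <- if (j < length(y)) {
      a <- abs(y[j]); b <- abs(y[j + 1])
      t_of(j) + (a - lev1) / (a - b) / rate
    } else t_of(j)
    # split: positive-to-negative zero crossing between the lobe peaks
    zc <- which(y[pk_pos:(pk_neg - 1)] > 0 & y[(pk_pos + 1):pk_neg] <= 0)
    if (!length(zc))
      stop("cycle-count error: no stand-to-sit lobe in a detected cycle")
    iz <- pk_pos + zc[1] - 1L
    ttm <- t_of(iz) + y[iz] / (y[iz] - y[iz + 1]) / rate
    cyc[[k]] <- list(i0 = max(i - 1L, 1L), im = iz, i1 = j,
                     t0 = tt0, tm = ttm, t1 = ttm1)
  }
  trans <- do.call(rbind, lapply(seq_along(cyc), function(k) {
    z <- cyc[[k]]
    data.frame(cycle = k, start = z$t0, split = z$tm, end = z$t1,
               sit_stand = z$tm - z$t0,
               stand_sit = z$t1 - z$tm,
               sit_stand_sit = z$t1 - z$t0)
  }))
  phase_stats <- function(sel) {
    vals <- lapply(cyc, function(z) {
      idx <- switch(sel, sit_stand = z$i0:z$im, stand_sit = z$im:z$i1,
                    sit_stand_sit = z$i0:z$i1)
      seg <- y[idx]
      c(mean_av = mean(abs(seg)), max_av = max(abs(seg)),
        jerk = jerk_measure(seg, rate))
    })
    colMeans(do.call(rbind, vals))
  }
  measures <- list()
  for (ph in c("sit_stand", "stand_sit", "sit_stand_sit")) {
    st <- phase_stats(ph)
    measures[[paste0("sts5_duration_", ph)]] <- mean(trans[[ph]])
    measures[[paste0("sts5_mean_av_", ph)]] <- st[["mean_av"]]
    measures[[paste0("sts5_max_av_", ph)]] <- st[["max_av"]]
    measures[[paste0("sts5_jerk_", ph)]] <- st[["jerk"]]
  }
  list(transitions = trans, measures = measures)
}

#' Limits-of-stability (forward reach) measures
#'
#' The reach distance is passed through from metadata when measured
#' externally; otherwise it is estimated as `height * sin(peak trunk pitch
#' excursion)` (flagged via the `reach_estimated` element).  RMS and jerk
#' of the low-back angular velocity are emitted per axis over the trial.
#'
#' @param low_back Low-back [sensor_recording()].
#' @param reach_distance Externally measured reach in m, or NA.
#' @param height_cm Subject height, used only for the estimate.
#' @return Named list of the `los_*` catalogue measures plus
#'   `reach_estimated`.
#' @export
los_measures <- function(low_back, reach_distance = NA, height_cm = NA) {
  rate <- low_back$sampling_rate
  lb <- filter_recording(low_back)
  out <- list()
  estimated <- FALSE
  if (is.na(reach_distance)) {
    if (!is.na(height_cm)) {
      th <- tilt_angles(low_back)
      excursion <- max(th$theta_ap) - th$theta_ap[1]
      reach_distance <- (height_cm / 100) * sin(pmax(excursion, 0) * pi / 180)
      estimated <- TRUE
    } else reach_distance <- NA_real_
  }
  out$los_reach_distance <- reach_distance
  for (nm in c(ap = "x", ml = "y", v = "z")) {
    dir <- names(which(c(ap = "x", ml = "y", v = "z") == nm))
    out[[paste0("los_rms_gyro_", dir)]] <- rms_amplitude(lb$gyro[, nm])
    out[[paste0("los_jerk_gyro_", dir)]] <- jerk_measure(lb$gyro[, nm], rate)
  }
  out$reach_estimated <- estimated
  out
}

#' Knee range of motion from paired leg sensors
#'
#' The knee angle is the difference between lower-leg and upper-leg sagittal
#' orientation.  When orientation channels are present their pitch angles
#' are used; otherwise each segment angle is obtained by integrating the
#' sagittal angular velocity with a linear detrend over the trial to
#' suppress gyro drift.  ROM is max minus min of the knee angle.
#'
#' @param upper_leg,lower_leg [sensor_recording()]s on the same side.
#' @param task `"flexion"` or `"extension"` (informational).
#' @return ROM in degrees.
#' @export
knee_rom <- function(upper_leg, lower_leg, task = c("flexion", "extension")) {
  task <- match.arg(task)
  seg_angle <- function(rec) {
    if (!is.null(rec$orientation)) return(rec$orientation[, "pitch"])
    if (all(rec$gyro[, "y"] == 0) && is.null(rec$orientation))
      return(rep(0, length(rec$time)))
    a <- cumsum(rec$gyro[, "y"]) / rec$sampling_rate
    fit <- lm.fit(cbind(1, rec$time), a)
    a - fit$fitted.values + mean(a)   # remove linear drift, keep scale
  }
  ang <- seg_angle(lower_leg) - seg_angle(upper_leg)
  if (!length(ang) || all(!is.finite(ang)))
    stop("knee angle unusable: no orientation and no usable gyro")
  max(ang) - min(ang)
}

#' Choice-reaction-test measures
#'
#' Simple reaction time is the mean RT over correct single-alternative
#' trials; information processing speed is `log2(n_alternatives)` divided
#' by the mean correct choice RT, in bits per second, averaged over choice
#' blocks (groups of trials sharing `n_alternatives > 1`).
#'
#' @param log An [app_log()] of kind CRT.
#' @return List with `crt_simple_reaction_time` (s) and
#'   `crt_information_processing_speed` (bit/s).
#' @export
crt_measures <- function(log) {
  stopifnot(inherits(log, "app_log"), log$kind == "CRT")
  tr <- log$trials
  ok <- tr[tr$correct, , drop = FALSE]
  if (!nrow(ok)) stop("no correct trials")
  simple <- ok[ok$n_alternatives == 1, , drop = FALSE]
  choice <- ok[ok$n_alternatives > 1, , drop = FALSE]
  if (!nrow(simple)) stop("no correct single-alternative trials")
  if (!nrow(choice)) stop("no correct multi-alternative trials")
  ips <- vapply(split(choice, choice$n_alternatives), function(blk) {
    log2(blk$n_alternatives[1]) / mean(blk$rt_s)
  }, numeric(1))
  list(crt_simple_reaction_time = mean(simple$rt_s),
       crt_information_processing_speed = mean(ips))
}

#' Falls-efficacy-scale score
#'
#' Sum of the item scores (7-item short form, items 1-4 by default); a
#' higher score means a greater fear of falling.
#'
#' @param log An [app_log()] of kind FES.
#' @return Integer total score.
#' @export
fes_score <- function(log) {
  stopifnot(inherits(log, "app_log"), log$kind == "FES")
  if (length(log$items) != log$n_items)
    stop(sprintf("missing FES item(s): expected %d, got %d (items %s)",
                 log$n_items, length(log$items),
                 paste(setdiff(seq_len(log$n_items),
                               seq_along(log$items)), collapse = ", ")))
  sum(log$items)
}

extract_sit_condition <- function(sess, config = list()) {
  lb <- sess$recordings[["low_back"]]
  rate <- lb$sampling_rate
  flt <- filter_recording(lb)
  th <- tilt_angles(lb)
  cond <- tolower(sub("^SIT_", "", sess$subtest))
  out <- list()
  p <- function(x) sprintf("sit_%s_%s", cond, x)
  for (dir in c(ap = "x", ml = "y")) {
    nm <- names(which(c(ap = "x", ml = "y") == dir))
    acc <- flt$acc[, dir]
    gy <- flt$gyro[, dir]
    theta <- if (nm == "ap") th$theta_ap else th$theta_ml
    out[[p(paste0("es_", nm))]] <-
      equilibrium_score(theta, config$theta_limit %||% 12.5)
    out[[p(paste0("rms_acc_", nm))]] <- rms_amplitude(acc)
    out[[p(paste0("rms_gyro_", nm))]] <- rms_amplitude(gy)
    out[[p(paste0("jerk_acc_", nm))]] <- jerk_measure(acc, rate)
    out[[p(paste0("jerk_gyro_", nm))]] <- jerk_measure(gy, rate)
    fa <- frequency_measures(acc, rate)
    fg <- frequency_measures(gy, rate)
    out[[p(paste0("medfreq_acc_", nm))]] <- fa$median_freq
    out[[p(paste0("cenfreq_acc_", nm))]] <- fa$centroid_freq
    out[[p(paste0("power_acc_", nm))]] <- fa$total_power
    out[[p(paste0("medfreq_gyro_", nm))]] <- fg$median_freq
    out[[p(paste0("cenfreq_gyro_", nm))]] <- fg$centroid_freq
    out[[p(paste0("power_gyro_", nm))]] <- fg$total_power
    out[[p(paste0("rms_tilt_", nm))]] <- rms_amplitude(theta)
    out[[p(paste0("sway_range_", nm))]] <- max(theta) - min(theta)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the full measure vector for one subject
#'
#' Runs every extractor the supplied sessions and app logs allow and
#' assembles one row of the 155-measure catalogue.  Absent subtests yield
#' NA entries (missingness is recorded, not an error), so partial batteries
#' are allowed.
#'
#' @param sessions Named list of [session()] objects keyed by subtest, or a
#'   plain list (subtests are read from the objects).
#' @param logs Named list with optional elements `CRT` and `FES`
#'   ([app_log()]s).
#' @param subject Optional [subject_record()] (used for the LOS reach
#'   estimate).
#' @param config Optional list of tuning parameters (`theta_limit`,
#'   `walkway_distance_m`, detector thresholds).
#' @return Named numeric vector of length 155 (`measure_vector` class) with
#'   attributes `subject_id` and `missing` (character vector of absent ids).
#' @export
extract_all <- function(sessions, logs = list(), subject = NULL,
                        config = list()) {
  cat_df <- measure_catalogue()
  vals <- setNames(rep(NA_real_, nrow(cat_df)), cat_df$measure_id)
  if (length(sessions) && is.null(names(sessions)))
    names(sessions) <- vapply(sessions, function(s) s$subtest, character(1))

  es <- list(ap = c(), ml = c())
  for (cond in SIT_CONDITIONS) {
    s <- sessions[[cond]]
    if (is.null(s)) next
    m <- extract_sit_condition(s, config)
    vals[names(m)] <- unlist(m)
    key <- tolower(sub("^SIT_", "", cond))
    es$ap[key] <- m[[sprintf("sit_%s_es_ap", key)]]
    es$ml[key] <- m[[sprintf("sit_%s_es_ml", key)]]
  }
  for (dir in c("ap", "ml")) {
    if (length(es[[dir]]) == 4L) {
      sc <- sensory_system_scores(es[[dir]])
      vals[sprintf("sit_som_%s", dir)] <- sc[["som"]]
      vals[sprintf("sit_vis_%s", dir)] <- sc[["vis"]]
      vals[sprintf("sit_vest_%s", dir)] <- sc[["vest"]]
    }
  }

  if (!is.null(sessions[["LOS"]])) {
    s <- sessions[["LOS"]]
    m <- los_measures(s$recordings[["low_back"]],
                      reach_distance = s$metadata$reach_distance_m %||% NA,
                      height_cm = subject$height_cm %||% NA)
    m$reach_estimated <- NULL
    vals[names(m)] <- unlist(m)
  }

  if (!is.null(sessions[["STS5"]])) {
    s <- sessions[["STS5"]]
    loc <- resolve_location("upper_leg", names(s$recordings))
    m <- sts5_measures(s$recordings[[loc]], config)$measures
    vals[names(m)] <- unlist(m)
  }

  if (!is.null(sessions[["TUG"]])) {
    s <- sessions[["TUG"]]
    ev <- detect_gait_events(s$recordings[["left_lower_leg"]],
                             s$recordings[["right_lower_leg"]],
                             params = config)
    ev <- detect_turn(ev, s$recordings[["low_back"]], params = config)
    wd <- s$metadata$walkway_distance_m %||% config$walkway_distance_m %||% 3
    m <- gait_measures(ev, s$recordings[["low_back"]], wd)
    m <- m[names(m) %in% cat_df$measure_id]
    vals[names(m)] <- unlist(m)
  }

  for (task in c("MF_FLEXION", "MF_EXTENSION")) {
    if (!is.null(sessions[[task]])) {
      s <- sessions[[task]]
      ul <- resolve_location("upper_leg", names(s$recordings))
      ll <- resolve_location("lower_leg", names(s$recordings))
      rom <- knee_rom(s$recordings[[ul]], s$recordings[[ll]],
                      tolower(sub("^MF_", "", task)))
      vals[if (task == "MF_FLEXION") "mf_knee_flexion_rom"
           else "mf_knee_extension_rom"] <- rom
    }
  }

  if (!is.null(logs$CRT)) {
    m <- crt_measures(logs$CRT)
    vals[names(m)] <- unlist(m)
  }
  if (!is.null(logs$FES)) vals["fes_score"] <- fes_score(logs$FES)

  structure(vals, class = c("measure_vector", "numeric"),
            subject_id = subject$subject_id %||% sessions[[1]]$subject_id %||% NA,
            missing = names(vals)[is.na(vals)])
}
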