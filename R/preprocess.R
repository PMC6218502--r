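#' Zero-phase low-pass Butterworth filter
#'
#' All raw channels are smoothed with a fourth-order low-pass Butterworth
#' filter with a 20 Hz cutoff before feature extraction.  The filter is
#' applied with zero phase so detected event times are not shifted; the
#' magnitude response of the zero-phase (two-pass) filter at frequency f is
#' `1 / (1 + (f/fc)^(2*order))`.  The response is realized exactly by
#' frequency-domain multiplication on an odd-reflection-padded copy of the
#' series, which avoids both phase distortion and bilinear frequency
#' warping near the Nyquist rate.
#'
#' @param x Numeric series sampled uniformly at `rate`.
#' @param rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency fc in Hz (must be < rate/2).
#' @param order Butterworth order of the underlying single-pass filter
#'   (default 4).
#' @param pad Reflection padding length in samples; default one second of
#'   signal (at least 3 x order), capped at `length(x) - 1`.
#' @return Filtered series, same length as `x`.
#' @export
butterworth_lowpass <- function(x, rate, cutoff = 20, order = 4, pad = NULL) {
  n <- length(x)
  if (n <= 3 * order)
    stop(sprintf("length error: series of length %d too short for order %d",
                 n, order))
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("spec error: cutoff must lie in (0, rate/2)")
  if (is.null(pad)) pad <- max(3L * order, round(rate))
  pad <- min(as.integer(pad), n - 1L)
  # odd reflection keeps value and slope continuous at the joins
  front <- 2 * x[1] - x[(pad + 1):2]
  back  <- 2 * x[n] - x[(n - 1):(n - pad)]
  xx <- c(front, x, back)
  m <- length(xx)
  f <- seq_len(m) - 1L
  f <- pmin(f, m - f) * rate / m           # two-sided frequency axis
  gain <- 1 / (1 + (f / cutoff)^(2 * order))
  y <- Re(fft(fft(xx) * gain, inverse = TRUE)) / m
  y[(pad + 1):(pad + n)]
}

#' Numerical time derivative
#'
#' Central differences in the interior, one-sided differences at the edges.
#' A linear ramp of slope k maps to the constant k everywhere.
#'
#' @param x Numeric series.
#' @param rate Sampling rate in Hz.
#' @return Series of the same length, in units of `x` per second.
#' @export
derivative <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("length error: derivative needs at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}

#' Trunk tilt angles from a low-back recording
#'
#' Anteroposterior and mediolateral tilt of the trunk, used for the
#' equilibrium score.  When the recording carries orientation channels the
#' pitch/roll Euler angles are used directly; otherwise the inclination of
#' the gravity vector is estimated from the low-pass-filtered acceleration:
#' `theta_AP = atan2(acc_x, acc_z)`, `theta_ML = atan2(acc_y, acc_z)`.
#'
#' @param low_back A [sensor_recording()] at the `low_back` location.
#' @param gravity_cutoff_hz Low-pass cutoff isolating the gravity component
#'   of acceleration (default 0.5 Hz); only used on the acceleration route.
#' @return List with numeric series `theta_ap` and `theta_ml` in degrees.
#' @export
tilt_angles <- function(low_back, gravity_cutoff_hz = 0.5) {
  stopifnot(inherits(low_back, "sensor_recording"))
  if (low_back$location != "low_back")
    stop("validation error: tilt_angles requires the low_back recording")
  if (!is.null(low_back$orientation)) {
    return(list(theta_ap = low_back$orientation[, "pitch"],
                theta_ml = low_back$orientation[, "roll"]))
  }
  rate <- low_back$sampling_rate
  g <- apply(low_back$acc, 2, butterworth_lowpass, rate = rate,
             cutoff = gravity_cutoff_hz, order = 4)
  list(theta_ap = atan2(g[, "x"], g[, "z"]) * 180 / pi,
       theta_ml = atan2(g[, "y"], g[, "z"]) * 180 / pi)
}

# filter every acc/gyro channel of a recording; returns a new recording
filter_recording <- function(rec, cutoff = 20, order = 4) {
  out <- rec
  out$acc <- apply(rec$acc, 2, butterworth_lowpass, rate = rec$sampling_rate,
                   cutoff = cutoff, order = order)
  out$gyro <- apply(rec$gyro, 2, butterworth_lowpass, rate = rec$sampling_rate,
                    cutoff = cutoff, order = order)
  colnames(out$acc) <- colnames(out$gyro) <- c("x", "y", "z")
  out
}
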