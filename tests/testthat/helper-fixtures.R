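# fixtures built in code; all tiny and deterministic

make_recording <- function(location = "low_back", n = 200, rate = 100,
                           acc = NULL, gyro = NULL, ...) {
  if (!is.null(acc)) n <- nrow(acc)
  if (!is.null(gyro)) n <- nrow(gyro)
  zero <- matrix(0, n, 3)
  if (is.null(acc)) { acc <- zero; acc[, 3] <- 9.81 }
  if (is.null(gyro)) gyro <- zero
  sensor_recording(location, acc = acc, gyro = gyro, sampling_rate = rate, ...)
}

make_tug_session <- function(seed = 1, noise_sd = 0, n_steps = 12,
                             stride = 1.0, ...) {
  simulate_tug(gait_profile(n_steps = n_steps, stride_time = stride,
                            noise_sd = noise_sd, ...), seed = seed)
}

# closed-form binormal AUC for two normal score distributions
binormal_auc <- function(mu1, sd1, mu2, sd2) {
  pnorm(abs(mu2 - mu1) / sqrt(sd1^2 + sd2^2))
}

# brute-force AUC oracle: explicit double loop over all pairs
auc_bruteforce <- function(scores, labels, positive = "faller") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  a <- s / (length(pos) * length(neg))
  max(a, 1 - a)
}

# two-group cohort data.frame from iid normals
null_cohort <- function(n1 = 114, n2 = 82, d = 2, seed = 1) {
  set.seed(seed)
  df <- data.frame(fall_status = c(rep("non_faller", n1), rep("faller", n2)))
  for (j in seq_len(d)) df[[paste0("f", j)]] <- rnorm(n1 + n2)
  df
}
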