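test_that("fall-status rule matches the labelling criteria and is monotone", {
  expect_equal(classify_fall_status(2, FALSE), "faller")
  expect_equal(classify_fall_status(1, TRUE), "faller")
  expect_equal(classify_fall_status(1, FALSE), "non_faller")
  expect_equal(classify_fall_status(0, FALSE), "non_faller")
  # injurious flag without any fall does not label a faller
  expect_equal(classify_fall_status(0, TRUE), "non_faller")
  expect_error(classify_fall_status(-1, FALSE), "non-negative")
  # monotonicity: adding falls never turns a faller into a non-faller
  for (inj in c(TRUE, FALSE)) {
    st <- classify_fall_status(0:6, inj)
    expect_false(any(st[-length(st)] == "faller" & st[-1] == "non_faller"))
  }
})

test_that("subject_record derives BMI and fall status consistently", {
  r <- subject_record("s1", 72, 155, 58, 2, FALSE)
  expect_equal(r$bmi, 58 / 1.55^2, tolerance = 1e-10)
  expect_equal(r$fall_status, "faller")
})

test_that("session round-trips through the CSV format losslessly", {
  sim <- make_tug_session(seed = 3, noise_sd = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session(sim$session, path)
  back <- read_session(path)
  expect_s3_class(back, "session")
  expect_setequal(names(back$recordings), names(sim$session$recordings))
  for (loc in names(sim$session$recordings)) {
    a <- sim$session$recordings[[loc]]
    b <- back$recordings[[loc]]
    expect_equal(b$sampling_rate, a$sampling_rate)
    expect_equal(b$acc, a$acc, tolerance = 1e-9)
    expect_equal(b$gyro, a$gyro, tolerance = 1e-9)
  }
  expect_equal(back$metadata$walkway_distance_m,
               sim$session$metadata$walkway_distance_m)
})

test_that("optional channels are omitted and recovered faithfully", {
  sw <- simulate_sway(sway_profile(), seed = 2)   # has orientation, no mag
  path <- withr::local_tempfile(fileext = ".csv")
  write_session(sw$session, path)
  hdr <- names(read.csv(path, nrows = 1))
  expect_false(any(grepl("^mag_", hdr)))
  back <- read_session(path)
  expect_equal(back$recordings$low_back$orientation,
               sw$session$recordings$low_back$orientation, tolerance = 1e-9)
})

test_that("format violations are reported by name", {
  sim <- make_tug_session(seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session(sim$session, path)
  df <- read.csv(path)
  df$gyro_y <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_session(path), "gyro_y")
})

test_that("dropped samples raise a sampling error listing gap indices", {
  sw <- simulate_sway(sway_profile(duration = 10), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session(sw$session, path)
  df <- read.csv(path)
  df <- df[-c(100, 500), ]            # two dropped samples
  write.csv(df, path, row.names = FALSE)
  err <- tryCatch(read_session(path), error = conditionMessage)
  expect_match(err, "sampling error")
  expect_match(err, "gap indices")
  expect_match(err, "99")             # gap right before the removed row
})

test_that("empty recordings and wrong locations are rejected", {
  expect_error(session("s", "TUG", list()), "empty recordings")
  rec <- make_recording("low_back")
  expect_error(session("s", "TUG", list(low_back = rec)), "left_lower_leg")
  expect_error(session("s", "SIT_EO_FIRM",
                       list(left_lower_leg = make_recording("left_lower_leg"))),
               "low_back")
})

test_that("recordings validate uniform sampling and finiteness", {
  acc <- matrix(0, 50, 3); acc[, 3] <- 9.81
  expect_error(
    sensor_recording("low_back", acc, matrix(0, 50, 3),
                     time = c(seq(0, 0.3, by = 0.01), seq(0.5, 0.68, by = 0.01)),
                     sampling_rate = 100),
    "sampling error")
  acc[10, 1] <- NA
  expect_error(sensor_recording("low_back", acc, matrix(0, 50, 3)),
               "non-finite")
})

test_that("app logs validate their structure", {
  expect_error(app_log("CRT", trials = data.frame(rt_s = 0.5)), "missing")
  expect_error(app_log("CRT", trials = data.frame(n_alternatives = 2,
                                                  rt_s = -1, correct = TRUE)),
               "positive")
  expect_error(app_log("FES", items = c(1, 2, 9)), "lie in")
  log <- app_log("FES", items = rep(2L, 7))
  expect_equal(fes_score(log), 14)
})
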