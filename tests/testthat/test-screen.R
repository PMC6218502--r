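# frozen oracle values: pooled t-tests on the published demographic
# summaries must reproduce the printed p-values (0.608, 0.577, 0.006, 0.001)

test_that("summary t-test reproduces the published demographic p-values", {
  expect_equal(ttest_from_summary(72.02, 4.17, 114,
                                  72.35, 4.74, 82)$p, 0.608, tolerance = 0.01)
  expect_equal(ttest_from_summary(154.83, 5.01, 114,
                                  154.41, 5.31, 82)$p, 0.577, tolerance = 0.01)
  expect_equal(round(ttest_from_summary(58.01, 6.93, 114,
                                        61.01, 8.05, 82)$p, 3), 0.006)
  expect_equal(round(ttest_from_summary(24.21, 2.74, 114,
                                        25.56, 2.93, 82)$p, 3), 0.001)
  tt <- ttest_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(tt$df, 18)
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("sample t-test agrees with the summary route and base R", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    a <- ttest_from_samples(x, y)
    b <- ttest_from_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y))
    expect_equal(a$t, b$t, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(a$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(a$p, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(ttest_from_samples(1:3, 1:3)$p, 1)
  expect_lt(ttest_from_samples(rnorm(20), rnorm(20) + 100)$p, 1e-6)
  # symmetry and affine invariance
  x <- rnorm(12); y <- rnorm(15, 0.5)
  expect_equal(ttest_from_samples(x, y)$p, ttest_from_samples(y, x)$p)
  expect_equal(abs(ttest_from_samples(3 * x + 7, 3 * y + 7)$t),
               abs(ttest_from_samples(x, y)$t), tolerance = 1e-10)
})

test_that("empirical AUC equals the brute-force pairwise oracle exactly", {
  set.seed(32)
  for (i in 1:200) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    scores <- c(sample(1:6, n1, TRUE), sample(1:6, n0, TRUE)) # ties likely
    labels <- c(rep("faller", n1), rep("non_faller", n0))
    expect_identical(roc_auc(scores, labels)$auc,
                     auc_bruteforce(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(33)
  scores <- rnorm(60)
  labels <- sample(c("faller", "non_faller"), 60, TRUE)
  a0 <- roc_auc(scores, labels)$auc
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3,
                 function(x) atan(x)))
    expect_equal(roc_auc(f(scores), labels)$auc, a0, tolerance = 1e-12)
})

test_that("AUC edge cases behave as documented", {
  labels <- c(rep("faller", 5), rep("non_faller", 5))
  expect_equal(roc_auc(c(6:10, 1:5), labels)$auc, 1.0)
  r <- roc_auc(rep(1, 10), labels)
  expect_equal(r$auc, 0.5)
  # orientation: lower-is-worse measures report direction -1
  r2 <- roc_auc(c(1:5, 6:10), labels)
  expect_equal(r2$auc, 1.0)
  expect_equal(r2$direction, -1)
  expect_error(roc_auc(1:5, rep("faller", 5)), "both classes")
})

test_that("screening selects by the t-and-ROC intersection rule", {
  set.seed(34)
  n1 <- 40; n2 <- 40
  df <- data.frame(fall_status = c(rep("faller", n1), rep("non_faller", n2)),
                   strong = c(rnorm(n1, 2), rnorm(n2)),   # clear effect
                   null1 = rnorm(n1 + n2), null2 = rnorm(n1 + n2))
  scr <- screen_measures(df)
  expect_true(scr$selected[scr$measure_id == "strong"])
  expect_true(all(!scr$selected | (scr$significant_t & scr$significant_roc)))
  expect_true(all(scr$p >= 0 & scr$p <= 1))
  expect_true(all(scr$auc >= 0.5 & scr$auc <= 1))
  # perfect separation on a single measure
  df2 <- data.frame(fall_status = df$fall_status,
                    sep = c(rnorm(n1, 10), rnorm(n2)))
  expect_true(screen_measures(df2)$selected)
  expect_error(screen_measures(data.frame(fall_status = rep("faller", 10),
                                          x = rnorm(10))), "both classes")
})

test_that("t-test size is nominal under the null", {
  # matched null at the cohort sizes; 2000 vectorized replicates
  set.seed(35)
  B <- 2000; n1 <- 114; n2 <- 82
  x <- matrix(rnorm(B * n1), B); y <- matrix(rnorm(B * n2), B)
  p <- vapply(seq_len(B), function(b) ttest_from_samples(x[b, ], y[b, ])$p,
              numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("measure ranking puts signal first and is reproducible", {
  set.seed(36)
  n <- 160
  y <- sample(c("faller", "non_faller"), n, TRUE)
  df <- data.frame(fall_status = y,
                   signal = (y == "faller") + rnorm(n, 0, 0.3),
                   noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  rk <- rank_measures(df, c("signal", "noise1", "noise2", "noise3"),
                      seed = 2, ntree = 200)
  expect_equal(rk$measure_id[1], "signal")
  expect_gt(rk$mda[1], 5)
  # pure-noise features have importance near zero
  expect_lt(max(abs(rk$mda[rk$measure_id != "signal"])), 5)
  rk2 <- rank_measures(df, c("signal", "noise1", "noise2", "noise3"),
                       seed = 2, ntree = 200)
  expect_identical(rk, rk2)
  expect_error(rank_measures(df, character(0)), "empty")
})
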