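# Six faller classification models sharing a common fit/predict interface.
# All models consume a standardized, mean-imputed numeric matrix prepared
# from the training folds only; the positive class is "faller" throughout.

#' The six faller classification model identifiers
#' @format Character vector.
#' @export
MODEL_IDS <- c("logistic_regression", "naive_bayes", "decision_tree",
               "boosted_tree", "random_forest", "svm")

#' Model specification
#'
#' @param model_id One of `logistic_regression`, `naive_bayes`,
#'   `decision_tree`, `boosted_tree`, `random_forest`, `svm`.
#' @param hyperparameters Named list overriding the defaults: decision
#'   tree `cp` 0.01, `min_node` 7; random forest `ntree` 500, `mtry`
#'   sqrt(d); boosted tree `n_stages` 100, `max_depth` 3, `learning_rate`
#'   0.1; SVM radial-basis kernel with `cost` 1 and `gamma` 1/d on
#'   standardized features.
#' @param seed Integer seed for the stochastic learners.
#' @return A `model_spec` list.
#' @export
model_spec <- function(model_id, hyperparameters = list(), seed = 1) {
  model_id <- match.arg(model_id, MODEL_IDS)
  defaults <- switch(model_id,
    logistic_regression = list(),
    naive_bayes = list(sd_floor = 1e-6),
    decision_tree = list(cp = 0.01, min_node = 7, max_depth = 30),
    boosted_tree = list(n_stages = 100, max_depth = 3, learning_rate = 0.1,
                        min_node = 10),
    random_forest = list(ntree = 500, mtry = NA, min_node = 5, max_depth = 25),
    svm = list(cost = 1, gamma = NA))
  structure(list(model_id = model_id,
                 hyperparameters = modifyList(defaults, hyperparameters),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# --- preprocessing fitted on training data only ---------------------------

fit_preproc <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  Xi <- X
  for (j in seq_len(ncol(Xi))) Xi[!is.finite(Xi[, j]), j] <- mu[j]
  sdv <- apply(Xi, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, center = colMeans(Xi), scale = sdv)
}

apply_preproc <- function(pp, X) {
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- pp$mu[j]
  scale(X, center = pp$center, scale = pp$scale)[, , drop = FALSE]
}

# --- individual learners --------------------------------------------------

fit_logistic <- function(X, y, hp, seed) {
  fit <- suppressWarnings(glm.fit(cbind(1, X), y,
                                  family = stats::binomial()))
  list(coef = ifelse(is.na(coef(fit)), 0, coef(fit)))
}
predict_logistic <- function(m, X) {
  eta <- drop(cbind(1, X) %*% m$coef)
  1 / (1 + exp(-eta))
}

fit_nb <- function(X, y, hp, seed) {
  stats_for <- function(cls) {
    Xc <- X[y == cls, , drop = FALSE]
    list(mu = colMeans(Xc), sd = pmax(apply(Xc, 2, sd), hp$sd_floor))
  }
  list(pos = stats_for(1), neg = stats_for(0),
       prior = mean(y))
}
predict_nb <- function(m, X) {
  ll <- function(st) {
    out <- numeric(nrow(X))
    for (j in seq_len(ncol(X)))
      out <- out + stats::dnorm(X[, j], st$mu[j], st$sd[j], log = TRUE)
    out
  }
  lp <- ll(m$pos) + log(m$prior)
  ln <- ll(m$neg) + log(1 - m$prior)
  1 / (1 + exp(ln - lp))
}

# basic decision tree with cost-complexity pruning: the complexity
# parameter is chosen by internal 5-fold CV with a one-SE rule (the most
# complex model is only kept if simpler ones are clearly worse), so on
# label-free data the tree collapses to the majority-class root
fit_tree <- function(X, y, hp, seed) {
  grow <- function(Xt, yt, cp, sd2) {
    .cart_grow(Xt, yt, rep(1, length(yt)), TRUE, hp$max_depth,
               as.integer(hp$min_node), as.integer(2 * hp$min_node + 6),
               -1L, cp, as.integer(sd2))
  }
  cp_grid <- hp$cp_grid %||% c(1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01, 0.005, 0.001)
  n <- length(y)
  kf <- min(5L, n)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(kf), n))
  acc <- matrix(NA_real_, kf, length(cp_grid))
  for (f in seq_len(kf)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) { acc[f, ] <- mean(y[!tr] == round(mean(y[tr]))); next }
    for (ci in seq_along(cp_grid)) {
      m <- grow(X[tr, , drop = FALSE], y[tr], cp_grid[ci], seed + f)
      ph <- as.numeric(.cart_predict(m, X[!tr, , drop = FALSE]) > 0.5)
      acc[f, ci] <- mean(ph == y[!tr])
    }
  }
  mu <- colMeans(acc)
  best <- which.max(mu)
  se <- sd(acc[, best]) / sqrt(kf)
  cp <- cp_grid[which(mu >= mu[best] - se)[1]]   # largest adequate cp
  grow(X, y, cp, seed)
}
predict_tree <- function(m, X) .cart_predict(m, X)

fit_rf <- function(X, y, hp, seed) {
  mtry <- if (is.na(hp$mtry)) max(1L, floor(sqrt(ncol(X)))) else hp$mtry
  .forest_grow(X, y, as.integer(hp$ntree), as.integer(mtry),
               as.integer(hp$min_node), as.integer(hp$max_depth),
               as.integer(seed))
}
predict_rf <- function(m, X) .forest_predict(m, X)

# gradient boosting with logistic loss and shallow regression trees on the
# pointwise negative gradient; Newton leaf updates
fit_gbm <- function(X, y, hp, seed) {
  n <- length(y)
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  F0 <- log(p0 / (1 - p0))
  Fv <- rep(F0, n)
  trees <- vector("list", hp$n_stages)
  gammas <- vector("list", hp$n_stages)
  w1 <- rep(1, n)
  for (m in seq_len(hp$n_stages)) {
    p <- 1 / (1 + exp(-Fv))
    r <- y - p
    tr <- .cart_grow(X, r, w1, FALSE, as.integer(hp$max_depth),
                     as.integer(hp$min_node), as.integer(2 * hp$min_node),
                     -1L, 0, as.integer(seed + m))
    leaf <- .cart_apply(tr, X)
    num <- tapply(r, leaf, sum)
    den <- tapply(p * (1 - p), leaf, sum)
    g <- num / pmax(den, 1e-6)
    gm <- setNames(as.numeric(g), names(num))
    Fv <- Fv + hp$learning_rate * gm[as.character(leaf)]
    trees[[m]] <- tr
    gammas[[m]] <- gm
  }
  list(F0 = F0, trees = trees, gammas = gammas, lr = hp$learning_rate)
}
predict_gbm <- function(m, X) {
  Fv <- rep(m$F0, nrow(X))
  for (k in seq_along(m$trees)) {
    leaf <- .cart_apply(m$trees[[k]], X)
    g <- m$gammas[[k]][as.character(leaf)]
    g[is.na(g)] <- 0
    Fv <- Fv + m$lr * g
  }
  1 / (1 + exp(-Fv))
}

# C-SVC with RBF kernel solved as the box-constrained dual QP
fit_svm <- function(X, y, hp, seed) {
  n <- nrow(X)
  gamma <- if (is.na(hp$gamma)) 1 / ncol(X) else hp$gamma
  ys <- 2 * y - 1
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-gamma * d2)
  Dmat <- (ys %o% ys) * K
  diag(Dmat) <- diag(Dmat) + 1e-8
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-hp$cost, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), hp$cost)
  sv <- alpha > 1e-8
  margin <- sv & alpha < hp$cost - 1e-8
  f_no_b <- drop(K %*% (alpha * ys))
  b <- if (any(margin)) mean(ys[margin] - f_no_b[margin])
       else mean(ys[sv] - f_no_b[sv])
  list(Xsv = X[sv, , drop = FALSE], coef = (alpha * ys)[sv], b = b,
       gamma = gamma)
}
predict_svm <- function(m, X) {
  d2 <- outer(rowSums(X^2), rowSums(m$Xsv^2), "+") - 2 * X %*% t(m$Xsv)
  f <- drop(exp(-m$gamma * pmax(d2, 0)) %*% m$coef) + m$b
  1 / (1 + exp(-f))   # monotone squash; 0.5 threshold equals sign(f)
}

fit_model_raw <- function(spec, X, y) {
  hp <- spec$hyperparameters
  fitter <- switch(spec$model_id,
    logistic_regression = fit_logistic, naive_bayes = fit_nb,
    decision_tree = fit_tree, boosted_tree = fit_gbm,
    random_forest = fit_rf, svm = fit_svm)
  fitter(X, y, hp, spec$seed)
}

predict_model_raw <- function(spec, fit, X) {
  pred <- switch(spec$model_id,
    logistic_regression = predict_logistic, naive_bayes = predict_nb,
    decision_tree = predict_tree, boosted_tree = predict_gbm,
    random_forest = predict_rf, svm = predict_svm)
  pred(fit, X)
}

#' Stratified cross-validation folds
#'
#' Stratified partition of the subjects into `k` folds (class proportions
#' within one subject per fold), repeated `repeats` times, deterministic
#' given the seed.  If a class is smaller than `k`, a warning is issued
#' and a plain (unstratified) partition is used.
#'
#' @param labels Class label vector.
#' @param k Number of folds (default 10).
#' @param repeats Number of repetitions (default 1).
#' @param seed Integer seed.
#' @return Integer matrix `length(labels)` x `repeats` of fold ids.
#' @export
make_folds <- function(labels, k = 10, repeats = 1, seed = 1) {
  n <- length(labels)
  if (n < k) stop("need at least k subjects")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  counts <- table(labels)
  stratified <- all(counts >= k)
  if (!stratified)
    warning("a class is smaller than k; falling back to a plain partition")
  out <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    set.seed((as.numeric(seed) * 131071 + r) %% 2147483647)
    if (stratified) {
      # distribute each class evenly; remainders go to the currently
      # smallest folds so total fold sizes stay within one subject
      totals <- integer(k)
      for (cls in names(sort(counts, decreasing = TRUE))) {
        idx <- sample(which(labels == cls))
        nc <- length(idx)
        per <- rep(nc %/% k, k)
        rem <- nc %% k
        if (rem > 0) {
          take <- order(totals + runif(k) * 0.1)[seq_len(rem)]
          per[take] <- per[take] + 1L
        }
        totals <- totals + per
        out[idx, r] <- rep(seq_len(k), per)
      }
    } else {
      out[sample(n), r] <- rep_len(seq_len(k), n)
    }
  }
  out
}

#' Cross-validated evaluation of one classification model
#'
#' For each fold (times repeats): fit on the other k-1 folds —
#' standardization and mean imputation are fitted on the training folds
#' only — predict the held-out subjects, and score accuracy, sensitivity
#' (correctly identified fallers) and specificity (correctly identified
#' non-fallers), all in percent with faller as the positive class.
#'
#' @param spec A [model_spec()].
#' @param features Labelled feature table (columns: optional `subject_id`,
#'   `fall_status`, numeric measures) or a numeric matrix.
#' @param folds Fold matrix from [make_folds()]; if NULL, a 10-fold
#'   stratified scheme seeded from the spec is used.
#' @param measures Optional character vector restricting the predictors.
#' @return A `model_evaluation` list: `model_id`, `per_fold` data.frame
#'   (repeat, fold, accuracy, sensitivity, specificity), and `summary`
#'   (mean and SD of each metric).
#' @export
evaluate_model <- function(spec, features, folds = NULL, measures = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  status <- features$fall_status
  ids <- measures %||% setdiff(names(features), c("subject_id", "fall_status"))
  X <- as.matrix(features[ids])
  if (ncol(X) < 2) stop("need at least 2 predictors")
  y <- as.numeric(status == "faller")
  if (is.null(folds)) folds <- make_folds(status, 10, 1, spec$seed)

  res <- list()
  for (r in seq_len(ncol(folds))) {
    fr <- folds[, r]
    for (f in sort(unique(fr))) {
      tr <- fr != f
      te <- !tr
      if (length(unique(y[tr])) < 2)
        stop("fold with a single class in training")
      pp <- fit_preproc(X[tr, , drop = FALSE])
      Xtr <- apply_preproc(pp, X[tr, , drop = FALSE])
      Xte <- apply_preproc(pp, X[te, , drop = FALSE])
      fit <- fit_model_raw(spec, Xtr, y[tr])
      ph <- as.numeric(predict_model_raw(spec, fit, Xte) > 0.5)
      yt <- y[te]
      acc <- 100 * mean(ph == yt)
      sens <- if (any(yt == 1)) 100 * mean(ph[yt == 1] == 1) else NA_real_
      spc <- if (any(yt == 0)) 100 * mean(ph[yt == 0] == 0) else NA_real_
      res[[length(res) + 1L]] <- data.frame(
        rep = r, fold = f, accuracy = acc, sensitivity = sens,
        specificity = spc)
    }
  }
  per_fold <- do.call(rbind, res)
  summ <- vapply(c("accuracy", "sensitivity", "specificity"), function(mname) {
    v <- per_fold[[mname]]
    c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  }, numeric(2))
  structure(list(model_id = spec$model_id, per_fold = per_fold,
                 repeats = ncol(folds), summary = summ),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<model_evaluation> %s (%d repeat(s)): accuracy %.2f +/- %.2f%%, sensitivity %.2f +/- %.2f%%, specificity %.2f +/- %.2f%%\n",
    x$model_id, x$repeats, s["mean", "accuracy"], s["sd", "accuracy"],
    s["mean", "sensitivity"], s["sd", "sensitivity"],
    s["mean", "specificity"], s["sd", "specificity"]))
  invisible(x)
}

#' Compare a reference model's CV accuracy against others
#'
#' Pooled two-sample t-tests on the per-fold accuracy distributions of the
#' reference model versus each competitor, reporting the mean difference,
#' its 95% CI and the two-sided p-value.  Evaluations must share the fold
#' scheme and repeat count.
#'
#' @param reference A `model_evaluation`.
#' @param others List of `model_evaluation`s.
#' @return data.frame: `model_id`, `delta_accuracy`, `ci_lo`, `ci_hi`, `p`.
#' @export
compare_models <- function(reference, others) {
  stopifnot(inherits(reference, "model_evaluation"))
  if (inherits(others, "model_evaluation")) others <- list(others)
  a <- reference$per_fold$accuracy
  rows <- lapply(others, function(ev) {
    stopifnot(inherits(ev, "model_evaluation"))
    b <- ev$per_fold$accuracy
    if (length(b) != length(a))
      stop("mismatched fold counts between evaluations")
    tt <- ttest_from_samples(a, b)
    delta <- mean(a) - mean(b)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / tt$df
    se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    ci <- delta + c(-1, 1) * stats::qt(0.975, tt$df) * se
    data.frame(model_id = ev$model_id, delta_accuracy = delta,
               ci_lo = ci[1], ci_hi = ci[2], p = tt$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
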