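#' Pooled two-sample t-test from group summaries
#'
#' Student (pooled-variance) two-sample t-test computed from per-group
#' mean, SD and n, as used for the 155-measure univariate screen; the
#' pooled form reproduces the published demographic p-values where the
#' Welch form does not.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df` (= n1 + n2 - 2) and two-sided `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    t <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
    return(list(t = t, df = df, p = if (t == 0) 1 else 0))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pooled two-sample t-test from raw samples
#'
#' Identical to [ttest_from_summary()] applied to the samples' own
#' summaries.
#'
#' @param x,y Numeric vectors (each length >= 2; NAs dropped).
#' @return List with `t`, `df`, `p`.
#' @export
ttest_from_samples <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  ttest_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Empirical ROC AUC with Hanley-McNeil standard error
#'
#' AUC is the fraction of (positive, negative) pairs ordered correctly,
#' ties counted one half (computed via the rank/Wilcoxon identity).  The
#' AUC is oriented to be >= 0.5 and the orientation recorded.  The
#' standard error uses the Hanley-McNeil formula, and the measure counts
#' as discriminative (`significant`) when the 95% CI excludes 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Vector with two classes; `positive` names the positive
#'   one.
#' @param positive Positive class label (default `"faller"`).
#' @return List with `auc` (oriented), `direction` (+1 if positives score
#'   higher), `se`, `ci95`, `significant`.
#' @export
roc_auc <- function(scores, labels, positive = "faller") {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc >= 0.5) 1 else -1
  a <- max(auc, 1 - auc)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
               (n1 * n0))
  ci <- c(a - 1.96 * se, a + 1.96 * se)
  list(auc = a, direction = direction, se = se, ci95 = ci,
       significant = ci[1] > 0.5)
}

#' Univariate screening of a labelled feature table
#'
#' For every measure column, a pooled two-sample t-test between fallers
#' and non-fallers and an ROC analysis; a measure is `selected` when it is
#' significant on both (t-test p below `alpha` and the AUC 95% CI
#' excluding 0.5).  `marginal` flags 0.05 <= p < 0.10.  An optional
#' Benjamini-Hochberg correction is available but off by default, matching
#' the raw-p screening convention.
#'
#' @param features data.frame with a `fall_status` column plus numeric
#'   measure columns.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per measure: `measure_id`, `t`, `df`,
#'   `p`, `auc`, `auc_se`, `auc_direction`, `significant_t`, `marginal`,
#'   `significant_roc`, `selected`.
#' @export
screen_measures <- function(features, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot("fall_status" %in% names(features))
  status <- features$fall_status
  if (length(unique(status)) < 2) stop("both classes must be present")
  ids <- setdiff(names(features), c("subject_id", "fall_status"))
  ids <- ids[vapply(features[ids], is.numeric, logical(1))]
  rows <- lapply(ids, function(id) {
    v <- features[[id]]
    f <- v[status == "faller"]
    nf <- v[status == "non_faller"]
    tt <- ttest_from_samples(f, nf)
    rc <- roc_auc(v, status)
    data.frame(measure_id = id, t = tt$t, df = tt$df, p = tt$p,
               auc = rc$auc, auc_se = rc$se, auc_direction = rc$direction,
               significant_roc = rc$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_eff <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant_t <- p_eff < alpha
  out$marginal <- p_eff >= alpha & p_eff < 0.10
  out$selected <- out$significant_t & out$significant_roc
  out
}

#' Rank screened measures by random-forest permutation importance
#'
#' Mean decrease accuracy: the drop in out-of-bag accuracy when a
#' measure's column is permuted, averaged over the trees of a random
#' forest grown on the selected measures.  The ranking sorts by MDA
#' descending with ties broken by AUC and then by t-test p-value.
#'
#' @param features Labelled feature table (as in [screen_measures()]).
#' @param selected Character vector of measure ids to rank (non-empty).
#' @param seed Integer seed.
#' @param ntree Number of trees (default 500).
#' @return data.frame sorted by rank: `measure_id`, `mda` (percentage
#'   points of OOB accuracy), `auc`, `p`, `rank`.
#' @export
rank_measures <- function(features, selected, seed = 1, ntree = 500) {
  if (!length(selected)) stop("selected measure set is empty")
  stopifnot(all(selected %in% names(features)))
  status <- features$fall_status
  if (sum(status == "faller") < 2 || sum(status == "non_faller") < 2)
    stop("need at least 2 subjects per class")
  X <- as.matrix(features[selected])
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- mean(X[!bad, j])
  }
  y <- as.numeric(status == "faller")
  fr <- .forest_grow(X, y, ntree = ntree,
                     mtry = max(1L, floor(sqrt(ncol(X)))),
                     min_node = 1L, max_depth = 25L, seed = as.integer(seed))
  mda <- 100 * .forest_mda(fr, X, y, as.integer(seed))
  scr <- screen_measures(features[c("fall_status", selected)])
  scr <- scr[match(selected, scr$measure_id), ]
  out <- data.frame(measure_id = selected, mda = mda, auc = scr$auc,
                    p = scr$p, stringsAsFactors = FALSE)
  ord <- order(-out$mda, -out$auc, out$p)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
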