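#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> extract -> screen -> classify
#' pipeline with defaults equal to the documented design choices.
#'
#' @param n_nonfaller,n_faller Synthetic cohort sizes.
#' @param seed Master seed.
#' @param simulate Generate the battery (TRUE) or read sessions from
#'   `input_dir`.
#' @param input_dir Directory of session CSVs when `simulate = FALSE`.
#' @param out_dir Output directory.
#' @param sway_duration SIT trial length, s.
#' @param filter Filter settings: `order`, `cutoff_hz`.
#' @param theta_limit Equilibrium-score stability limit, deg.
#' @param walkway_distance_m TUG walkway length, m.
#' @param alpha Screening significance level.
#' @param cv_k,cv_repeats Cross-validation scheme.
#' @param models Model ids to evaluate (default all six).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_nonfaller = 10, n_faller = 10, seed = 1,
                            simulate = TRUE, input_dir = NULL,
                            out_dir = tempfile("fallrisk_run_"),
                            sway_duration = 30,
                            filter = list(order = 4, cutoff_hz = 20),
                            theta_limit = 12.5, walkway_distance_m = 3,
                            alpha = 0.05, cv_k = 5, cv_repeats = 2,
                            models = MODEL_IDS) {
  structure(list(n_nonfaller = n_nonfaller, n_faller = n_faller, seed = seed,
                 simulate = simulate, input_dir = input_dir,
                 out_dir = out_dir, sway_duration = sway_duration,
                 filter = filter, theta_limit = theta_limit,
                 walkway_distance_m = walkway_distance_m, alpha = alpha,
                 cv_k = cv_k, cv_repeats = cv_repeats, models = models),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' Simulates (or loads) a cohort battery, extracts the 155-measure vector
#' per subject, screens the measures, ranks the selected set by
#' permutation importance, evaluates the requested classifiers under
#' repeated stratified cross-validation, and writes `features.csv`,
#' `screening.csv`, `evaluation.json` and a human-readable `report.txt`
#' to the output directory.  Identical config and seeds give identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `features`, `screening`, `ranking`,
#'   `evaluations`, `comparisons` and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage 1: sessions -------------------------------------------------
  if (config$simulate) {
    say("[simulate] %d non-fallers + %d fallers (seed %d)",
        config$n_nonfaller, config$n_faller, config$seed)
    bat <- simulate_battery(config$n_nonfaller, config$n_faller,
                            seed = config$seed,
                            sway_duration = config$sway_duration)
  } else {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop(sprintf("path error: input directory '%s' does not exist",
                   config$input_dir %||% "<unset>"))
    stop("reading a recorded cohort needs per-subject session manifests; ",
         "see read_session()")
  }

  # --- stage 2: features -------------------------------------------------
  say("[extract] %d subjects x 155 measures", length(bat$subjects))
  feats <- lapply(bat$subjects, function(su) {
    mv <- tryCatch(
      extract_all(su$sessions, su$logs, su$record,
                  config = list(theta_limit = config$theta_limit,
                                walkway_distance_m = config$walkway_distance_m)),
      error = function(e) stop(sprintf("stage 'extract', subject %s: %s",
                                       su$record$subject_id,
                                       conditionMessage(e))))
    c(list(subject_id = su$record$subject_id,
           fall_status = su$record$fall_status), as.list(mv))
  })
  features <- do.call(rbind, lapply(feats, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  f_feat <- file.path(config$out_dir, "features.csv")
  write.csv(features, f_feat, row.names = FALSE)

  # --- stage 3: screening ------------------------------------------------
  screening <- screen_measures(features, alpha = config$alpha)
  sel <- screening$measure_id[screening$selected]
  say("[screen] %d of %d measures selected", length(sel), nrow(screening))
  ranking <- if (length(sel) >= 1)
    rank_measures(features, sel, seed = config$seed) else NULL
  f_scr <- file.path(config$out_dir, "screening.csv")
  scr_out <- screening
  scr_out$mda_rank <- NA_integer_
  if (!is.null(ranking))
    scr_out$mda_rank[match(ranking$measure_id, scr_out$measure_id)] <- ranking$rank
  write.csv(scr_out, f_scr, row.names = FALSE)

  # --- stage 4: classification ------------------------------------------
  predictors <- if (length(sel) >= 2) sel else screened_reference()
  folds <- make_folds(features$fall_status, k = config$cv_k,
                      repeats = config$cv_repeats, seed = config$seed)
  evaluations <- lapply(config$models, function(mid) {
    say("[classify] %s", mid)
    evaluate_model(model_spec(mid, seed = config$seed), features,
                   folds = folds, measures = predictors)
  })
  names(evaluations) <- config$models
  comparisons <- if ("svm" %in% config$models && length(evaluations) > 1) {
    compare_models(evaluations[["svm"]],
                   evaluations[setdiff(names(evaluations), "svm")])
  } else NULL
  f_eval <- file.path(config$out_dir, "evaluation.json")
  jsonlite::write_json(list(
    models = lapply(evaluations, function(ev) list(
      model_id = ev$model_id, per_fold = ev$per_fold,
      summary = as.data.frame(t(ev$summary)))),
    comparisons = comparisons), f_eval, auto_unbox = TRUE, digits = NA,
    null = "null")

  # --- stage 5: report ---------------------------------------------------
  f_rep <- file.path(config$out_dir, "report.txt")
  write_report(f_rep, bat$demographics, screening, ranking, evaluations,
               comparisons, config)
  say("[done] %.1f s -> %s", as.numeric(Sys.time()) - as.numeric(t_start),
      config$out_dir)
  invisible(list(features = features, screening = screening,
                 ranking = ranking, evaluations = evaluations,
                 comparisons = comparisons,
                 paths = c(features = f_feat, screening = f_scr,
                           evaluation = f_eval, report = f_rep)))
}

write_report <- function(path, demo, screening, ranking, evaluations,
                         comparisons, config) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("fall-risk pipeline report (seed %d)", config$seed)
  w("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  w("")
  w("== cohort demographics (mean +/- SD, pooled two-sample t-test) ==")
  for (v in c("age", "height_cm", "weight_kg", "bmi")) {
    nf <- demo[[v]][demo$fall_status == "non_faller"]
    f <- demo[[v]][demo$fall_status == "faller"]
    tt <- ttest_from_samples(nf, f)
    w("%-10s non-faller %7.2f +/- %5.2f | faller %7.2f +/- %5.2f | p = %.3f",
      v, mean(nf), sd(nf), mean(f), sd(f), tt$p)
  }
  w("")
  w("== screening: %d of %d measures significant on both t-test and ROC ==",
    sum(screening$selected), nrow(screening))
  if (!is.null(ranking)) {
    w("top measures by mean decrease accuracy:")
    top <- head(ranking, 10)
    for (i in seq_len(nrow(top)))
      w("%2d. %-32s MDA %6.2f  AUC %.3f  p %.4f", top$rank[i],
        top$measure_id[i], top$mda[i], top$auc[i], top$p[i])
  }
  w("")
  w("== classification (%d-fold CV x %d repeat(s), faller positive) ==",
    config$cv_k, config$cv_repeats)
  for (ev in evaluations) {
    s <- ev$summary
    w("%-20s accuracy %5.1f +/- %4.1f%%  sensitivity %5.1f +/- %4.1f%%  specificity %5.1f +/- %4.1f%%",
      ev$model_id, s["mean", "accuracy"], s["sd", "accuracy"],
      s["mean", "sensitivity"], s["sd", "sensitivity"],
      s["mean", "specificity"], s["sd", "specificity"])
  }
  if (!is.null(comparisons)) {
    w("")
    w("== SVM accuracy vs other models (pooled t-test on per-fold accuracy) ==")
    for (i in seq_len(nrow(comparisons)))
      w("svm - %-20s delta %+5.1f%% (95%% CI %+5.1f to %+5.1f), p = %.4f",
        comparisons$model_id[i], comparisons$delta_accuracy[i],
        comparisons$ci_lo[i], comparisons$ci_hi[i], comparisons$p[i])
  }
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (emit session CSVs + ground truth for one
#' subtest), `run-all` (full pipeline), `screen` and `classify` (operate
#' on a features CSV).  Invoked by the `exec/fallrisk` script as
#' `fallrisk <subcommand> [--key value ...]`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly.
#' @export
fallrisk_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fallrisk <simulate|screen|classify|run-all> [options]",
    "  simulate --what tug|sway|sts5|cohort --seed N --out DIR",
    "  screen   --features f.csv --out screening.csv",
    "  classify --features f.csv --seed N --out eval.json [--models all|id,id]",
    "  run-all  [--config cfg.yaml|cfg.json] [--seed N] [--out DIR]",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list()
  kv <- args[-1]
  i <- 1
  while (i <= length(kv)) {
    if (grepl("^--", kv[i])) {
      opts[[sub("^--", "", kv[i])]] <- if (i < length(kv)) kv[i + 1] else ""
      i <- i + 2
    } else i <- i + 1
  }
  seed <- as.integer(opts$seed %||% 1)
  out <- opts$out %||% "fallrisk_out"

  if (cmd == "simulate") {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    what <- opts$what %||% "tug"
    if (what == "cohort") {
      df <- simulate_cohort_features(cohort_spec(seed = seed))
      write.csv(df, file.path(out, "cohort_features.csv"), row.names = FALSE)
    } else {
      sim <- switch(what,
        tug = simulate_tug(gait_profile(noise_sd = 5), seed = seed),
        sway = simulate_sway(sway_profile(), seed = seed),
        sts5 = simulate_sts5(rep(2, 5), seed = seed),
        stop("unknown simulate target: ", what))
      write_session(sim$session, file.path(out, paste0(what, ".csv")))
      jsonlite::write_json(unclass(sim$truth),
                           file.path(out, paste0(what, "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  } else if (cmd == "screen") {
    df <- read.csv(opts$features, stringsAsFactors = FALSE)
    write.csv(screen_measures(df), opts$out %||% "screening.csv",
              row.names = FALSE)
  } else if (cmd == "classify") {
    df <- read.csv(opts$features, stringsAsFactors = FALSE)
    mods <- opts$models %||% "all"
    mods <- if (mods == "all") MODEL_IDS else strsplit(mods, ",")[[1]]
    folds <- make_folds(df$fall_status, 10, 1, seed)
    evs <- lapply(mods, function(mid)
      evaluate_model(model_spec(mid, seed = seed), df, folds = folds))
    jsonlite::write_json(lapply(evs, function(ev)
      list(model_id = ev$model_id, per_fold = ev$per_fold)),
      opts$out %||% "eval.json", auto_unbox = TRUE, digits = NA)
  } else if (cmd == "run-all") {
    cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
           else pipeline_config(seed = seed, out_dir = out)
    if (!is.null(opts$seed)) cfg$seed <- seed
    if (!is.null(opts$out)) cfg$out_dir <- out
    run_pipeline(cfg)
  } else {
    cat(usage, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
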