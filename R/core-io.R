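#' @useDynLib fallrisk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef fft glm.fit lm.fit median pnorm pt qnorm rbinom
#'   rnorm runif sd setNames var
#' @importFrom utils head modifyList read.csv tail write.csv
NULL

#' Sensor locations and subtests of the test battery
#'
#' The battery uses five 9-DOF inertial sensors (low back, both upper legs,
#' both lower legs) sampled at 100 Hz, and nine recorded subtest conditions:
#' four quiet-standing sensory-integration conditions (eyes open/closed on a
#' firm/foam surface), limits of stability, five-times sit-to-stand, timed up
#' and go, and knee flexion/extension motor function.
#'
#' @format Character vectors of the canonical enum values.
#' @name battery-enums
NULL

#' @rdname battery-enums
#' @export
SENSOR_LOCATIONS <- c("low_back", "left_upper_leg", "right_upper_leg",
                      "left_lower_leg", "right_lower_leg")

#' @rdname battery-enums
#' @export
SUBTESTS <- c("SIT_EO_FIRM", "SIT_EC_FIRM", "SIT_EO_FOAM", "SIT_EC_FOAM",
              "LOS", "STS5", "TUG", "MF_FLEXION", "MF_EXTENSION")

#' @rdname battery-enums
#' @export
SIT_CONDITIONS <- c("SIT_EO_FIRM", "SIT_EC_FIRM", "SIT_EO_FOAM", "SIT_EC_FOAM")

axis_names <- c("x", "y", "z")   # x = anteroposterior, y = mediolateral, z = vertical

#' Sensor locations required by each subtest
#'
#' Sensor-to-subtest mapping: the low-back sensor serves the quiet-standing
#' and limits-of-stability tests, an upper-leg sensor serves sit-to-stand,
#' upper plus lower leg serve knee motor function, and timed up and go uses
#' the low back plus both lower legs.
#'
#' @param subtest One of [SUBTESTS].
#' @return Character vector of required locations; for STS5 and MF either
#'   body side is acceptable and alternatives are separated in list elements.
#' @export
required_locations <- function(subtest) {
  subtest <- match.arg(subtest, SUBTESTS)
  switch(subtest,
    SIT_EO_FIRM = , SIT_EC_FIRM = , SIT_EO_FOAM = , SIT_EC_FOAM = ,
    LOS = "low_back",
    STS5 = "upper_leg",
    TUG = c("low_back", "left_lower_leg", "right_lower_leg"),
    MF_FLEXION = , MF_EXTENSION = c("upper_leg", "lower_leg"))
}

# resolve a possibly side-free location requirement against available names
resolve_location <- function(req, available) {
  if (req %in% available) return(req)
  for (side in c("right", "left")) {
    cand <- paste(side, req, sep = "_")
    if (cand %in% available) return(cand)
  }
  NA_character_
}

as_channel_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop(sprintf("'%s' must have 3 columns (x, y, z)", what))
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, axis_names)
  m
}

#' Construct a sensor recording
#'
#' One sensor location's synchronized time series.  Axis convention:
#' x = anteroposterior, y = mediolateral, z = vertical for an upright
#' subject.  Acceleration is in m/s^2, angular velocity in deg/s,
#' orientation Euler angles (roll, pitch, yaw) in deg.
#'
#' @param location One of [SENSOR_LOCATIONS].
#' @param acc,gyro n x 3 numeric matrices (columns x, y, z).
#' @param time Optional time vector in seconds; defaults to a uniform grid
#'   at `sampling_rate`.
#' @param mag,orientation Optional n x 3 matrices (orientation columns are
#'   roll, pitch, yaw in deg).
#' @param sampling_rate Samples per second (default 100).
#' @return A `sensor_recording` object.
#' @export
sensor_recording <- function(location, acc, gyro, time = NULL, mag = NULL,
                             orientation = NULL, sampling_rate = 100) {
  location <- match.arg(location, SENSOR_LOCATIONS)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  acc <- as_channel_matrix(acc, "acc")
  gyro <- as_channel_matrix(gyro, "gyro")
  n <- nrow(acc)
  if (nrow(gyro) != n) stop("acc and gyro must have equal length")
  if (is.null(time)) time <- seq(0, by = 1 / sampling_rate, length.out = n)
  if (length(time) != n) stop("time and channels must have equal length")
  if (!is.null(mag)) {
    mag <- as_channel_matrix(mag, "mag")
    if (nrow(mag) != n) stop("mag length mismatch")
  }
  if (!is.null(orientation)) {
    orientation <- as.matrix(orientation)
    if (ncol(orientation) != 3L || nrow(orientation) != n)
      stop("orientation must be an n x 3 matrix (roll, pitch, yaw)")
    storage.mode(orientation) <- "double"
    dimnames(orientation) <- list(NULL, c("roll", "pitch", "yaw"))
  }
  rec <- structure(list(location = location, sampling_rate = sampling_rate,
                        time = as.numeric(time), acc = acc, gyro = gyro,
                        mag = mag, orientation = orientation),
                   class = "sensor_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec, time_tol = 1e-6) {
  n <- length(rec$time)
  if (n < 2) stop("recording must contain at least 2 samples")
  dt <- diff(rec$time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  gaps <- which(abs(dt - 1 / rec$sampling_rate) > time_tol)
  if (length(gaps))
    stop(sprintf(
      "sampling error: non-uniform timestamps at %d position(s) (gap indices: %s)",
      length(gaps), paste(head(gaps, 10L), collapse = ", ")))
  for (ch in c("acc", "gyro", "mag", "orientation")) {
    m <- rec[[ch]]
    if (!is.null(m) && !all(is.finite(m)))
      stop(sprintf("non-finite samples in channel '%s'", ch))
  }
  invisible(rec)
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s: %d samples @ %g Hz (%.2f s)%s%s\n",
              x$location, length(x$time), x$sampling_rate,
              diff(range(x$time)),
              if (!is.null(x$mag)) " +mag" else "",
              if (!is.null(x$orientation)) " +orientation" else ""))
  invisible(x)
}

#' Construct a session
#'
#' All recordings plus metadata for one subject performing one subtest.
#'
#' @param subject_id Opaque subject identifier.
#' @param subtest One of [SUBTESTS].
#' @param recordings Named list of [sensor_recording()] objects, keyed by
#'   location.
#' @param metadata Named list (e.g. `walkway_distance_m`, `surface`, `eyes`,
#'   `reach_distance_m`, `notes`).
#' @return A `session` object.
#' @export
session <- function(subject_id, subtest, recordings, metadata = list()) {
  subtest <- match.arg(subtest, SUBTESTS)
  if (!length(recordings)) stop("validation error: empty recordings map")
  if (is.null(names(recordings)) || any(names(recordings) == ""))
    stop("recordings must be a named list keyed by sensor location")
  for (nm in names(recordings)) {
    rec <- recordings[[nm]]
    if (!inherits(rec, "sensor_recording"))
      stop(sprintf("recordings[['%s']] is not a sensor_recording", nm))
    if (rec$location != nm)
      stop(sprintf("recording keyed '%s' has location '%s'", nm, rec$location))
  }
  for (req in required_locations(subtest)) {
    if (is.na(resolve_location(req, names(recordings))))
      stop(sprintf("subtest %s requires a recording at '%s'", subtest, req))
  }
  structure(list(subject_id = as.character(subject_id), subtest = subtest,
                 recordings = recordings, metadata = metadata),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> subject %s, subtest %s, sensors: %s\n",
              x$subject_id, x$subtest,
              paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}

#' Retrospective faller labelling rule
#'
#' A subject is labelled a faller when they experienced multiple falls, or
#' one injurious fall requiring medical attention, within the year prior to
#' assessment; everyone else is a non-faller.
#'
#' @param n_falls_past_year Non-negative fall count in the past year.
#' @param injurious_fall_past_year Logical; at least one fall required
#'   medical attention.
#' @return `"faller"` or `"non_faller"` (vectorized).
#' @export
classify_fall_status <- function(n_falls_past_year, injurious_fall_past_year) {
  n <- n_falls_past_year
  inj <- as.logical(injurious_fall_past_year)
  if (any(!is.finite(n)) || any(n < 0) || any(n != floor(n)))
    stop("validation error: n_falls_past_year must be a non-negative count")
  ifelse(n >= 2 | (inj & n >= 1), "faller", "non_faller")
}

#' Construct a subject record
#'
#' Demographics plus fall history; BMI and fall status are derived.
#'
#' @param subject_id Identifier.
#' @param age Years.
#' @param height_cm,weight_kg Anthropometrics.
#' @param n_falls_past_year Count of falls in the past year.
#' @param injurious_fall_past_year Logical.
#' @return A `subject_record` (named list) with derived `bmi` (kg/m^2) and
#'   `fall_status`.
#' @export
subject_record <- function(subject_id, age, height_cm, weight_kg,
                           n_falls_past_year, injurious_fall_past_year) {
  if (height_cm <= 0 || weight_kg <= 0) stop("height and weight must be positive")
  structure(list(
    subject_id = as.character(subject_id), age = age, height_cm = height_cm,
    weight_kg = weight_kg, bmi = weight_kg / (height_cm / 100)^2,
    n_falls_past_year = n_falls_past_year,
    injurious_fall_past_year = as.logical(injurious_fall_past_year),
    fall_status = classify_fall_status(n_falls_past_year,
                                       injurious_fall_past_year)),
    class = "subject_record")
}

#' Construct an app log
#'
#' Numeric logs of the two tablet-administered subtests: choice reaction
#' (CRT) trials and falls-efficacy-scale (FES) item scores.
#'
#' @param kind `"CRT"` or `"FES"`.
#' @param trials For CRT: data.frame with columns `n_alternatives`
#'   (count >= 1), `rt_s` (> 0) and `correct` (logical/0-1).
#' @param items For FES: integer item scores.
#' @param item_range Allowed FES item score range (default 1-4).
#' @param n_items Expected FES item count (default 7).
#' @return An `app_log` object.
#' @export
app_log <- function(kind = c("CRT", "FES"), trials = NULL, items = NULL,
                    item_range = c(1L, 4L), n_items = 7L) {
  kind <- match.arg(kind)
  if (kind == "CRT") {
    stopifnot(is.data.frame(trials))
    need <- c("n_alternatives", "rt_s", "correct")
    miss <- setdiff(need, names(trials))
    if (length(miss))
      stop(sprintf("CRT log missing column(s): %s", paste(miss, collapse = ", ")))
    if (any(trials$rt_s <= 0)) stop("reaction_time must be positive")
    if (any(trials$n_alternatives < 1)) stop("n_alternatives must be >= 1")
    trials$correct <- as.logical(trials$correct)
    structure(list(kind = kind, trials = trials), class = "app_log")
  } else {
    items <- as.integer(items)
    if (any(is.na(items)) ||
        any(items < item_range[1]) || any(items > item_range[2]))
      stop(sprintf("FES item scores must lie in [%d, %d]",
                   item_range[1], item_range[2]))
    structure(list(kind = kind, items = items, item_range = item_range,
                   n_items = as.integer(n_items)), class = "app_log")
  }
}

session_columns <- function(rec) {
  cols <- c("time_s", "location",
            paste0("acc_", axis_names), paste0("gyro_", axis_names))
  if (!is.null(rec$mag)) cols <- c(cols, paste0("mag_", axis_names))
  if (!is.null(rec$orientation))
    cols <- c(cols, "roll_deg", "pitch_deg", "yaw_deg")
  cols
}

#' Write a session to disk
#'
#' Sessions are stored as a UTF-8 CSV (one row per sample per sensor, with a
#' `location` column) plus a JSON sidecar `<path>.meta.json` carrying
#' subject id, subtest, sampling rate and metadata.  The round trip through
#' [read_session()] is lossless to 1e-9 relative tolerance.
#'
#' @param session A [session()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session"))
  blocks <- lapply(session$recordings, function(rec) {
    df <- data.frame(time_s = rec$time, location = rec$location,
                     rec$acc, rec$gyro, check.names = FALSE)
    names(df) <- c("time_s", "location",
                   paste0("acc_", axis_names), paste0("gyro_", axis_names))
    if (!is.null(rec$mag)) {
      m <- as.data.frame(rec$mag)
      names(m) <- paste0("mag_", axis_names)
      df <- cbind(df, m)
    }
    if (!is.null(rec$orientation)) {
      o <- as.data.frame(rec$orientation)
      names(o) <- c("roll_deg", "pitch_deg", "yaw_deg")
      df <- cbind(df, o)
    }
    df
  })
  all_cols <- Reduce(union, lapply(blocks, names))
  blocks <- lapply(blocks, function(df) {
    for (col in setdiff(all_cols, names(df))) df[[col]] <- NA_real_
    df[all_cols]
  })
  out <- do.call(rbind, blocks)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  out[out == "NA"] <- ""
  tryCatch(
    write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("I/O error writing '%s': %s", path,
                                     conditionMessage(e))))
  meta <- list(subject_id = session$subject_id, subtest = session$subtest,
               sampling_rate = session$recordings[[1]]$sampling_rate,
               metadata = session$metadata)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a session from disk
#'
#' Reads the columnar CSV format written by [write_session()].  A
#' `format_spec` may remap non-canonical column names (e.g. from another
#' export tool) onto the canonical ones via its `columns` element, a named
#' character vector `c(canonical = "actual")`, and may override
#' `sampling_rate`.
#'
#' @param path CSV path (expects `<path>.meta.json` sidecar; without it,
#'   `format_spec` must carry `subject_id`, `subtest` and `sampling_rate`).
#' @param format_spec Optional list; see Details.
#' @return A validated [session()].
#' @export
read_session <- function(path, format_spec = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(format_spec$columns)) {
    for (canon in names(format_spec$columns)) {
      actual <- format_spec$columns[[canon]]
      if (actual %in% names(df)) names(df)[names(df) == actual] <- canon
    }
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(subject_id = format_spec$subject_id, subtest = format_spec$subtest,
         sampling_rate = format_spec$sampling_rate, metadata = list())
  }
  if (is.null(meta$subject_id) || is.null(meta$subtest) ||
      is.null(meta$sampling_rate))
    stop("format error: missing session metadata (subject_id/subtest/sampling_rate)")
  rate <- if (!is.null(format_spec$sampling_rate)) format_spec$sampling_rate
          else meta$sampling_rate

  need <- c("time_s", "location",
            paste0("acc_", axis_names), paste0("gyro_", axis_names))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("format error: missing required column '%s'", miss[1]))

  has_mag <- all(paste0("mag_", axis_names) %in% names(df)) &&
    !all(is.na(df$mag_x))
  has_ori <- all(c("roll_deg", "pitch_deg", "yaw_deg") %in% names(df)) &&
    !all(is.na(df$roll_deg))

  recs <- lapply(split(df, df$location), function(blk) {
    blk <- blk[order(blk$time_s), , drop = FALSE]
    check_uniform_time(blk$time_s, rate)
    sensor_recording(
      location = blk$location[1],
      time = blk$time_s,
      acc = as.matrix(blk[paste0("acc_", axis_names)]),
      gyro = as.matrix(blk[paste0("gyro_", axis_names)]),
      mag = if (has_mag) as.matrix(blk[paste0("mag_", axis_names)]) else NULL,
      orientation = if (has_ori)
        as.matrix(blk[c("roll_deg", "pitch_deg", "yaw_deg")]) else NULL,
      sampling_rate = rate)
  })
  md <- meta$metadata
  if (is.null(md) || (is.list(md) && !length(md))) md <- list()
  session(meta$subject_id, meta$subtest, recs, as.list(md))
}

check_uniform_time <- function(time_s, rate, tol = 1e-6) {
  dt <- diff(time_s)
  gaps <- which(abs(dt - 1 / rate) > tol)
  if (length(gaps))
    stop(sprintf(
      "sampling error: declared %g Hz but %d irregular interval(s); gap indices: %s",
      rate, length(gaps), paste(head(gaps, 20L), collapse = ", ")))
  invisible(TRUE)
}

#' Read a cohort demographics table
#'
#' @param path CSV with columns `subject_id`, `age`, `height_cm`,
#'   `weight_kg`, `n_falls_past_year`, `injurious_fall` (0/1).
#' @return data.frame with derived `bmi` and `fall_status` columns.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "height_cm", "weight_kg",
            "n_falls_past_year", "injurious_fall")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("format error: missing required column '%s'", miss[1]))
  df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  df$fall_status <- classify_fall_status(df$n_falls_past_year,
                                         df$injurious_fall == 1)
  df
}

#' Read an app log CSV
#'
#' @param path CSV path. CRT columns: `trial`, `n_alternatives`, `rt_s`,
#'   `correct`; FES columns: `item`, `score`.
#' @param kind `"CRT"` or `"FES"`.
#' @return An [app_log()].
#' @export
read_app_log <- function(path, kind = c("CRT", "FES")) {
  kind <- match.arg(kind)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (kind == "CRT") {
    app_log("CRT", trials = df)
  } else {
    if (!all(c("item", "score") %in% names(df)))
      stop("format error: FES log needs columns 'item' and 'score'")
    app_log("FES", items = df$score[order(df$item)])
  }
}
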