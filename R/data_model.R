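# Domain types: sensor recordings, subject profiles, activity windows and
# session datasets, plus delimited-text session I/O and stream alignment.

#' Construct a sensor recording for one body site
#'
#' A `sensor_recording` holds the synchronised streams of one wearable module:
#' tri-axial acceleration (g), tri-axial angular velocity (deg/s) and
#' barometric altitude (m), on a common strictly increasing time base.
#'
#' @param site body-site code, one of `"wrist_L"`, `"wrist_R"`, `"ankle_L"`,
#'   `"ankle_R"`, `"foot_L"`, `"foot_R"`, `"chest"`, `"hip"`.
#' @param t numeric vector of timestamps in seconds from session start,
#'   strictly increasing.
#' @param acc n x 3 matrix of acceleration in g.
#' @param gyro n x 3 matrix of angular velocity in deg/s; for ankle sites the
#'   third column is rotation in the sagittal plane.
#' @param alt numeric vector of altitude in metres.
#' @param fs nominal sampling rate in Hz.
#' @return an object of class `sensor_recording`.
#' @export
sensor_recording <- function(site, t, acc, gyro, alt, fs) {
  site <- match.arg(site, SITES)
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  t <- as.numeric(t); alt <- as.numeric(alt)
  if (any(diff(t) <= 0)) {
    stop_iscee(sprintf("timestamps of site '%s' are not strictly increasing", site),
               "iscee_data_error")
  }
  n <- length(t)
  if (nrow(acc) != n || nrow(gyro) != n || length(alt) != n ||
      ncol(acc) != 3L || ncol(gyro) != 3L) {
    stop_iscee(sprintf("channel lengths of site '%s' disagree", site),
               "iscee_format_error")
  }
  if (!is.numeric(fs) || fs <= 0) stop_iscee("fs must be > 0", "iscee_format_error")
  structure(list(site = site, t = t, acc = acc, gyro = gyro, alt = alt,
                 fs = as.numeric(fs)),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> site %s: %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
              x$site, length(x$t), x$fs, x$t[1], x$t[length(x$t)]))
  invisible(x)
}

# Clinical scores carried as subject features, in fixed order. Values are
# consumed as plain numbers; AIS grades are encoded A=1 ... E=5 and the
# neurological level as an ordinal (C1=1 ... S5=30-ish scale chosen upstream).
SCORE_NAMES <- c("scim_total", "scim_mobility", "scim_selfcare", "scim_respiration",
                 "six_mwt_m", "ten_mwt_s", "tug_s",
                 "grassp_total", "grassp_strength", "grassp_sensibility",
                 "ais", "nli")

#' Construct a subject profile
#'
#' @param id subject identifier (character or integer).
#' @param age age in years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param weight body weight in kg.
#' @param height body height in m.
#' @param handedness `"left"` or `"right"`; resolves dominant vs non-dominant
#'   limb sites in feature names.
#' @param sport_hours_per_week reported hours of sport per week.
#' @param scores named numeric vector of clinical scores (see
#'   `iscee:::SCORE_NAMES`); missing entries are filled with `NA`.
#' @param ree_est estimated resting EE in kcal/day (optional).
#' @param ree_meas measured resting EE in kcal/day (optional).
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(id, age, sex, weight, height,
                            handedness = "right", sport_hours_per_week = 0,
                            scores = numeric(), ree_est = NA_real_,
                            ree_meas = NA_real_) {
  sex <- match.arg(sex, c("male", "female"))
  handedness <- match.arg(handedness, c("right", "left"))
  if (age < 18) stop_iscee("age must be >= 18", "iscee_data_error")
  if (weight <= 0 || height <= 0) {
    stop_iscee("weight and height must be > 0", "iscee_data_error")
  }
  for (v in c(ree_est, ree_meas)) {
    if (!is.na(v) && v <= 0) stop_iscee("REE values must be > 0", "iscee_data_error")
  }
  full <- setNames(rep(NA_real_, length(SCORE_NAMES)), SCORE_NAMES)
  if (length(scores)) {
    bad <- setdiff(names(scores), SCORE_NAMES)
    if (length(bad)) {
      stop_iscee(paste("unknown clinical score(s):", paste(bad, collapse = ", ")),
                 "iscee_format_error")
    }
    full[names(scores)] <- as.numeric(scores)
  }
  structure(list(id = as.character(id), age = as.numeric(age), sex = sex,
                 weight = as.numeric(weight), height = as.numeric(height),
                 handedness = handedness,
                 sport_hours_per_week = as.numeric(sport_hours_per_week),
                 scores = full, ree_est = as.numeric(ree_est),
                 ree_meas = as.numeric(ree_meas)),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: %s, %g y, %g kg, %.2f m, %s-handed\n",
              x$id, x$sex, x$age, x$weight, x$height, x$handedness))
  invisible(x)
}

#' Construct a labelled one-minute activity window
#'
#' @param subject_id id of the subject the window belongs to.
#' @param activity_name free-text activity name (e.g. `"walking_4kmh"`).
#' @param activity_class one of `"sedentary"`, `"low_intensity"`,
#'   `"high_intensity"`, `"walking"`.
#' @param window_index 0-based index of the window within its activity.
#' @param signals named list of [sensor_recording()] slices (one per site),
#'   each covering 60 s.
#' @param ee_meas measured EE in kcal/day (optional; required for model
#'   fitting).
#' @param steady_state logical; EE had reached a steady state.
#' @param complete logical; all expected sensor streams present.
#' @param truth optional list of simulator ground truth (step event times per
#'   leg, drawn MET, true speed, ...).
#' @return an object of class `activity_window`.
#' @export
activity_window <- function(subject_id, activity_name, activity_class,
                            window_index, signals, ee_meas = NA_real_,
                            steady_state = TRUE, complete = TRUE,
                            truth = NULL) {
  activity_class <- match.arg(activity_class, ACTIVITY_CLASSES)
  stopifnot(is.list(signals))
  for (rec in signals) {
    if (!inherits(rec, "sensor_recording")) {
      stop_iscee("signals must be sensor_recording objects", "iscee_format_error")
    }
    dur <- rec$t[length(rec$t)] - rec$t[1] + 1 / rec$fs
    if (abs(dur - 60) > 1.5 / rec$fs) {
      stop_iscee(sprintf("window signal at site '%s' does not span 60 s", rec$site),
                 "iscee_data_error")
    }
  }
  names(signals) <- vapply(signals, `[[`, "", "site")
  if (anyDuplicated(names(signals))) {
    stop_iscee("duplicate site within a window", "iscee_data_error")
  }
  structure(list(subject_id = as.character(subject_id),
                 activity_name = activity_name,
                 activity_class = activity_class,
                 window_index = as.integer(window_index),
                 signals = signals, ee_meas = as.numeric(ee_meas),
                 steady_state = isTRUE(steady_state),
                 complete = isTRUE(complete), truth = truth),
            class = "activity_window")
}

#' Construct a session dataset
#'
#' Bundles subject profiles with their labelled activity windows; every
#' window's `subject_id` must resolve to a profile.
#'
#' @param subjects list of [subject_profile()] objects.
#' @param windows list of [activity_window()] objects.
#' @return an object of class `session_dataset`.
#' @export
session_dataset <- function(subjects, windows) {
  ids <- vapply(subjects, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_iscee("duplicate subject ids", "iscee_data_error")
  names(subjects) <- ids
  for (w in windows) {
    if (!w$subject_id %in% ids) {
      stop_iscee(sprintf("window refers to unknown subject '%s'", w$subject_id),
                 "iscee_data_error")
    }
  }
  structure(list(subjects = subjects, windows = windows),
            class = "session_dataset")
}

#' @export
print.session_dataset <- function(x, ...) {
  cls <- table(factor(vapply(x$windows, `[[`, "", "activity_class"),
                      levels = ACTIVITY_CLASSES))
  cat(sprintf("<session_dataset> %d subjects, %d windows (%s)\n",
              length(x$subjects), length(x$windows),
              paste(sprintf("%s %d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

## ---- delimited-text session I/O -------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

subjects_to_df <- function(subjects) {
  if (!length(subjects)) return(NULL)
  rows <- lapply(subjects, function(s) {
    d <- data.frame(id = s$id, age = s$age, sex = s$sex, weight = s$weight,
                    height = s$height, handedness = s$handedness,
                    sport_hours_per_week = s$sport_hours_per_week,
                    ree_est = s$ree_est, ree_meas = s$ree_meas,
                    stringsAsFactors = FALSE)
    for (nm in SCORE_NAMES) d[[paste0("score_", nm)]] <- s$scores[[nm]]
    d
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

df_to_subjects <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    sc <- as.numeric(df[i, paste0("score_", SCORE_NAMES)])
    names(sc) <- SCORE_NAMES
    subject_profile(id = df$id[i], age = df$age[i], sex = df$sex[i],
                    weight = df$weight[i], height = df$height[i],
                    handedness = df$handedness[i],
                    sport_hours_per_week = df$sport_hours_per_week[i],
                    scores = sc[!is.na(sc)],
                    ree_est = df$ree_est[i], ree_meas = df$ree_meas[i])
  })
}

window_file_stem <- function(w) sprintf("%s_%s_w%d", w$subject_id,
                                        gsub("[^A-Za-z0-9]+", "-", w$activity_name),
                                        w$window_index)

#' Write a session dataset as a set of delimited text files
#'
#' Produces `subjects.csv`, `windows.csv`, one per-site time-series CSV per
#' window under `signals/`, and (when simulator ground truth is attached) a
#' `truth.json` sidecar. Numeric values are written with 17 significant
#' digits, so `read_session(write_session(x))` is lossless and a second write
#' is byte-identical.
#'
#' @param dataset a [session_dataset()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(dataset, path) {
  stopifnot(inherits(dataset, "session_dataset"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop_iscee(sprintf("cannot create '%s'", path), "iscee_io_error")
  dir.create(file.path(path, "signals"), showWarnings = FALSE)

  sdf <- subjects_to_df(dataset$subjects)
  if (is.null(sdf)) {
    sdf <- data.frame(id = character(), age = character(), sex = character(),
                      weight = character(), height = character(),
                      handedness = character(), sport_hours_per_week = character(),
                      ree_est = character(), ree_meas = character())
  } else {
    for (nm in setdiff(names(sdf), c("id", "sex", "handedness"))) {
      sdf[[nm]] <- fmt_num(sdf[[nm]])
    }
  }
  write.csv(sdf, file.path(path, "subjects.csv"), row.names = FALSE, quote = FALSE)

  wrows <- lapply(dataset$windows, function(w) {
    data.frame(subject_id = w$subject_id, activity_name = w$activity_name,
               activity_class = w$activity_class, window_index = w$window_index,
               ee_meas = fmt_num(w$ee_meas), steady_state = w$steady_state,
               complete = w$complete, fs = fmt_num(w$signals[[1]]$fs %||% NA_real_),
               sites = paste(names(w$signals), collapse = ";"),
               stem = window_file_stem(w), stringsAsFactors = FALSE)
  })
  wdf <- if (length(wrows)) do.call(rbind, c(wrows, list(make.row.names = FALSE)))
  if (is.null(wdf)) {
    wdf <- data.frame(subject_id = character(), activity_name = character(),
                      activity_class = character(), window_index = character(),
                      ee_meas = character(), steady_state = character(),
                      complete = character(), fs = character(),
                      sites = character(), stem = character())
  }
  write.csv(wdf, file.path(path, "windows.csv"), row.names = FALSE, quote = FALSE)

  truths <- list()
  for (w in dataset$windows) {
    stem <- window_file_stem(w)
    for (rec in w$signals) {
      df <- data.frame(t = fmt_num(rec$t),
                       acc_x = fmt_num(rec$acc[, 1]), acc_y = fmt_num(rec$acc[, 2]),
                       acc_z = fmt_num(rec$acc[, 3]),
                       gyro_x = fmt_num(rec$gyro[, 1]), gyro_y = fmt_num(rec$gyro[, 2]),
                       gyro_z = fmt_num(rec$gyro[, 3]), alt = fmt_num(rec$alt))
      write.csv(df, file.path(path, "signals", sprintf("%s_%s.csv", stem, rec$site)),
                row.names = FALSE, quote = FALSE)
    }
    if (!is.null(w$truth)) truths[[stem]] <- w$truth
  }
  if (length(truths)) {
    jsonlite::write_json(truths, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a session dataset written by [write_session()]
#'
#' @param path directory containing `subjects.csv`, `windows.csv` and
#'   `signals/`.
#' @return a [session_dataset()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop_iscee(sprintf("no such session '%s'", path),
                                    "iscee_io_error")
  sdf <- read.csv(file.path(path, "subjects.csv"), stringsAsFactors = FALSE)
  wdf <- read.csv(file.path(path, "windows.csv"), stringsAsFactors = FALSE)
  subjects <- if (nrow(sdf)) df_to_subjects(sdf) else list()
  tpath <- file.path(path, "truth.json")
  truths <- if (file.exists(tpath)) jsonlite::read_json(tpath, simplifyVector = TRUE) else list()
  windows <- lapply(seq_len(nrow(wdf)), function(i) {
    row <- wdf[i, ]
    sites <- strsplit(row$sites, ";", fixed = TRUE)[[1]]
    signals <- lapply(sites, function(site) {
      f <- file.path(path, "signals", sprintf("%s_%s.csv", row$stem, site))
      if (!file.exists(f)) {
        stop_iscee(sprintf("missing channel file for site '%s' of window '%s'",
                           site, row$stem), "iscee_format_error")
      }
      df <- read.csv(f)
      sensor_recording(site, df$t, as.matrix(df[c("acc_x", "acc_y", "acc_z")]),
                       as.matrix(df[c("gyro_x", "gyro_y", "gyro_z")]),
                       df$alt, fs = row$fs)
    })
    activity_window(row$subject_id, row$activity_name, row$activity_class,
                    row$window_index, signals, ee_meas = row$ee_meas,
                    steady_state = row$steady_state, complete = row$complete,
                    truth = truths[[row$stem]])
  })
  session_dataset(subjects, windows)
}

#' Resample recordings onto a common clock
#'
#' Linearly interpolates every recording onto one shared timestamp grid at
#' `target_fs`, spanning the overlap of all input time supports. No
#' extrapolation is performed beyond the original support.
#'
#' @param recordings list of [sensor_recording()] objects.
#' @param target_fs target sampling rate in Hz (default 50).
#' @return list of recordings sharing an identical time grid.
#' @export
align_streams <- function(recordings, target_fs = 50) {
  stopifnot(length(recordings) >= 1, target_fs > 0)
  t0 <- max(vapply(recordings, function(r) r$t[1], 0))
  t1 <- min(vapply(recordings, function(r) r$t[length(r$t)], 0))
  if (t1 <= t0) stop_iscee("recordings have no overlapping time support",
                           "iscee_alignment_error")
  grid <- seq(t0, t1, by = 1 / target_fs)
  lapply(recordings, function(r) {
    interp <- function(y) approx(r$t, y, xout = grid, method = "linear")$y
    sensor_recording(r$site, grid,
                     apply(r$acc, 2, interp), apply(r$gyro, 2, interp),
                     interp(r$alt), fs = target_fs)
  })
}
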