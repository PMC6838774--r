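# Per-window feature bank: single-sensor statistical features on acceleration
# magnitude (a_M), gyroscope magnitude (w_M), ankle sagittal angular velocity
# (w_Z) and altitude (H), plus high-level multi-sensor features, demographics
# and clinical scores. Feature names follow the STAT(signal_site) convention,
# e.g. "PERC_95(w_Z_DA)" = 95th percentile of the sagittal angular velocity at
# the dominant ankle.

BASE_STATS <- c("MEAN", "MEDIAN", "SD", "VAR", "RMS", "IQR",
                paste0("PERC_", c(1, 3, 5, 25, 75, 95, 99)))
ALT_STATS <- c("MEAN", "MEDIAN", "SD", "VAR", "RMS", "IQR",
               paste0("PERC_", c(25, 75, 95)))
ALT_STATS_ANKLE <- c(ALT_STATS, paste0("PERC_", c(1, 5, 99)))

SITE_CODES <- c(DW = "wrist", NDW = "wrist", DA = "ankle", NDA = "ankle",
                DF = "foot", NDF = "foot", Ch = "chest", Hi = "hip")

HIGH_LEVEL_FEATURES <- c("STEPS", "DIST", "STRIDE_VAR",
                         "LAT_upper", "LAT_lower_ankle", "LAT_feet",
                         "LAT_upper_vs_lower",
                         "CORR_wrists", "CORR_ankles", "CORR_feet",
                         "ALT_CHANGE", "AC_total")

DEMOGRAPHIC_FEATURES <- c("age", "sex", "weight", "height", "bmi",
                          "handedness", "sport_hours_per_week")

#' Resolve a dominant-side site code to a physical site
#'
#' `DW`/`NDW` (wrists), `DA`/`NDA` (ankles) and `DF`/`NDF` (feet) are resolved
#' from the subject's handedness; `Ch` and `Hi` map to chest and hip.
#'
#' @param code site code used in feature names.
#' @param handedness `"right"` or `"left"`.
#' @return a physical site name such as `"wrist_R"`.
#' @export
resolve_site <- function(code, handedness = "right") {
  if (!code %in% names(SITE_CODES)) {
    stop_iscee(sprintf("unknown site code '%s'", code), "iscee_config_error")
  }
  part <- SITE_CODES[[code]]
  if (part %in% c("chest", "hip")) return(part)
  dom <- if (handedness == "right") "R" else "L"
  nondom <- if (dom == "R") "L" else "R"
  paste0(part, "_", if (startsWith(code, "ND")) nondom else dom)
}

#' Parse a statistical feature name
#'
#' Round-trips the `STAT(signal_site)` grammar: `parse_feature_name()` splits
#' a name into its statistic, signal and site code, and
#' `format_feature_name()` rebuilds it.
#'
#' @param name feature name, e.g. `"MEAN(a_M_DW)"`.
#' @return list with elements `stat`, `signal`, `site_code`, or `NULL` when
#'   the name is not a statistical feature.
#' @export
parse_feature_name <- function(name) {
  m <- regmatches(name, regexec(
    "^([A-Z]+(?:_[0-9]+)?)\\((a_M|w_M|w_Z|H)_(DW|NDW|DA|NDA|DF|NDF|Ch|Hi)\\)$",
    name))[[1]]
  if (length(m) != 4) return(NULL)
  list(stat = m[2], signal = m[3], site_code = m[4])
}

#' @rdname parse_feature_name
#' @param stat,signal,site_code components of the name.
#' @export
format_feature_name <- function(stat, signal, site_code) {
  sprintf("%s(%s_%s)", stat, signal, site_code)
}

stat_names_for <- function(signal, site_code) {
  switch(signal,
    a_M = c(BASE_STATS, "AC"),
    w_M = BASE_STATS,
    w_Z = BASE_STATS,
    H = if (site_code %in% c("DA", "NDA")) ALT_STATS_ANKLE else ALT_STATS)
}

#' The default feature bank
#'
#' Enumerates the 351 feature names computed per window: per-site statistics
#' (36 for wrists, feet, chest and hip; 52 for ankles, which add the sagittal
#' angular velocity), 12 high-level features, 7 demographic features and 12
#' clinical scores. Resting EE is appended separately (EE models only).
#'
#' @return character vector of feature names.
#' @export
feature_bank <- function() {
  stat_names <- unlist(lapply(names(SITE_CODES), function(code) {
    signals <- c("a_M", "w_M", if (code %in% c("DA", "NDA")) "w_Z", "H")
    unlist(lapply(signals, function(sig) {
      vapply(stat_names_for(sig, code), format_feature_name, "",
             signal = sig, site_code = code)
    }))
  }))
  c(stat_names, HIGH_LEVEL_FEATURES, DEMOGRAPHIC_FEATURES, SCORE_NAMES)
}

#' Statistical summary features of a scalar series
#'
#' Mean, median, sample SD and variance (denominator n-1), RMS, IQR and the
#' 1st/3rd/5th/25th/75th/95th/99th percentiles (linear-interpolation
#' quantiles, R type 7).
#'
#' @param x numeric series of length >= 2.
#' @return named numeric vector of the 13 statistics.
#' @export
statistical_features <- function(x) {
  if (length(x) < 2) stop_iscee("series must have length >= 2", "iscee_data_error")
  qs <- quantile(x, probs = c(0.01, 0.03, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99),
                 names = FALSE, type = 7)
  v <- var(x)
  c(MEAN = mean(x), MEDIAN = qs[5], SD = sqrt(v), VAR = v,
    RMS = sqrt(mean(x^2)), IQR = qs[6] - qs[4],
    setNames(qs[-5], paste0("PERC_", c(1, 3, 5, 25, 75, 95, 99))))
}

#' Activity counts of a high-pass-filtered acceleration magnitude
#'
#' Time integral of the rectified signal, `sum(|x|)/fs`, in g*s over the
#' window. Device-independent and monotone in movement intensity; linear in
#' signal amplitude.
#'
#' @param x high-pass-filtered acceleration magnitude (g).
#' @param fs sampling rate in Hz.
#' @return activity counts in g*s.
#' @export
activity_counts <- function(x, fs) sum(abs(x)) / fs

#' Detect steps in an ankle sagittal-plane angular velocity signal
#'
#' The signal is low-pass filtered at 5 Hz (2nd-order Butterworth,
#' zero-phase); local maxima with height at least
#' `max(min_height, rel_height * P95)` and at least `refractory` seconds apart
#' are counted as steps of that leg. Candidate peaks are accepted in order of
#' decreasing height so that a large peak suppresses smaller neighbours
#' within the refractory gap.
#'
#' @param wz angular velocity (deg/s) about the sagittal axis of one ankle.
#' @param fs sampling rate in Hz.
#' @param min_height absolute peak-height floor in deg/s (default 20).
#' @param rel_height relative height threshold against the window's 95th
#'   percentile (default 0.3).
#' @param refractory minimum inter-peak gap in seconds (default 0.3).
#' @return numeric vector of step event times in seconds (possibly empty).
#' @export
detect_steps <- function(wz, fs, min_height = 20, rel_height = 0.3,
                         refractory = 0.3) {
  if (length(wz) <= 6) return(numeric())
  sm <- butterworth_filter(wz, fs, filter_spec("lowpass", 2, 5))
  n <- length(sm)
  thr <- max(min_height, rel_height * quantile(sm, 0.95, names = FALSE))
  idx <- which(sm[2:(n - 1)] >= sm[1:(n - 2)] & sm[2:(n - 1)] > sm[3:n]) + 1L
  idx <- idx[sm[idx] >= thr]
  if (!length(idx)) return(numeric())
  idx <- idx[order(sm[idx], decreasing = TRUE)]
  gap <- round(refractory * fs)
  kept <- integer()
  for (i in idx) {
    if (!length(kept) || all(abs(kept - i) >= gap)) kept <- c(kept, i)
  }
  sort(kept - 1L) / fs
}

#' Step length from body height (static method)
#'
#' `step_length = K * height` with K = 0.415 for men and 0.413 for women.
#'
#' @param subject a [subject_profile()].
#' @return step length in metres.
#' @export
step_length <- function(subject) {
  if (is.na(subject$height)) stop_iscee("height missing", "iscee_data_error")
  k <- if (subject$sex == "male") 0.415 else 0.413
  k * subject$height
}

#' Distance walked from a step count
#'
#' @param n_steps number of steps.
#' @param step_len step length in metres (see [step_length()]).
#' @return distance in metres.
#' @export
walk_distance <- function(n_steps, step_len) n_steps * step_len

#' Variance of stride time
#'
#' Sample variance of successive same-leg inter-step intervals, pooled over
#' both legs. Requires at least three steps on a leg for that leg to
#' contribute; returns `NA` when no leg qualifies (explicit missing-value
#' sentinel, never a silent zero).
#'
#' @param step_times_per_leg list of numeric vectors of step event times, one
#'   per leg.
#' @return pooled variance in s^2, or `NA`.
#' @export
stride_time_variance <- function(step_times_per_leg) {
  intervals <- unlist(lapply(step_times_per_leg, function(tt) {
    if (length(tt) >= 3) diff(sort(tt)) else numeric()
  }))
  if (length(intervals) < 2) return(NA_real_)
  var(intervals)
}

#' Limb-use laterality index
#'
#' Symmetric ratio index on activity counts,
#' `(AC_dom - AC_nondom) / (AC_dom + AC_nondom)`, in `[-1, 1]`; 0 when both
#' sides are inactive.
#'
#' @param ac_dom,ac_nondom non-negative activity counts of the dominant and
#'   non-dominant side.
#' @return laterality index.
#' @export
laterality_index <- function(ac_dom, ac_nondom) {
  tot <- ac_dom + ac_nondom
  if (tot == 0) return(0)
  (ac_dom - ac_nondom) / tot
}

#' Maximum normalised cross-correlation within +-1 s
#'
#' Both series are mean-removed; the normalised cross-correlation is scanned
#' over lags in `[-max_lag, +max_lag]` seconds and the maximum returned.
#' Zero-variance input yields 0 by convention.
#'
#' @param x,y equal-length numeric series.
#' @param fs sampling rate in Hz.
#' @param max_lag lag search half-width in seconds (default 1).
#' @return maximum correlation in `[-1, 1]`.
#' @export
cross_correlation_feature <- function(x, y, fs, max_lag = 1) {
  stopifnot(length(x) == length(y))
  x <- x - mean(x); y <- y - mean(y)
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) return(0)
  n <- length(x)
  L <- min(round(max_lag * fs), n - 1)
  # FFT cross-correlation; zero-padding by L makes lags |k| <= L exact
  xp <- c(x, rep(0, L))
  yp <- c(y, rep(0, L))
  cc <- convolve(xp, yp, conj = TRUE, type = "circular")
  m <- length(cc)
  lags <- (-L):L
  max(cc[((-lags) %% m) + 1]) / denom
}

#' Net altitude change over a window
#'
#' Last minus first sample of the low-pass-filtered altitude; signed, in
#' metres.
#'
#' @param alt filtered altitude series (m).
#' @return net change in metres.
#' @export
altitude_change <- function(alt) alt[length(alt)] - alt[1]

## ---- per-window assembly ---------------------------------------------------

# Filtered per-site series used by the statistical features.
site_series <- function(rec, cfg) {
  hp <- filter_spec("highpass", 2, cfg$accel_highpass_hz)
  lp <- filter_spec("lowpass", 2, cfg$altitude_lowpass_hz)
  acc_f <- butterworth_filter(rec$acc, rec$fs, hp)
  list(a_M = magnitude(acc_f), w_M = magnitude(rec$gyro),
       w_Z = rec$gyro[, 3], H = butterworth_filter(rec$alt, rec$fs, spec = lp))
}

#' Compute the full feature vector of one window
#'
#' @param window an [activity_window()].
#' @param subject the matching [subject_profile()].
#' @param cfg preprocessing configuration (see [preprocess_config()]).
#' @return named numeric vector over [feature_bank()]; features whose sensors
#'   are missing are `NA`.
#' @export
window_features <- function(window, subject, cfg = preprocess_config()) {
  bank <- feature_bank()
  out <- setNames(rep(NA_real_, length(bank)), bank)
  hand <- subject$handedness

  series <- list()
  ac_by_site <- setNames(rep(NA_real_, length(SITES)), SITES)
  for (code in names(SITE_CODES)) {
    site <- resolve_site(code, hand)
    rec <- window$signals[[site]]
    if (is.null(rec)) next
    if (is.null(series[[site]])) series[[site]] <- site_series(rec, cfg)
    ss <- series[[site]]
    for (sig in c("a_M", "w_M", if (code %in% c("DA", "NDA")) "w_Z", "H")) {
      wanted <- stat_names_for(sig, code)
      stats <- statistical_features(ss[[sig]])
      if ("AC" %in% wanted) {
        stats <- c(stats, AC = activity_counts(ss[[sig]], rec$fs))
      }
      nm <- vapply(wanted, format_feature_name, "", signal = sig, site_code = code)
      out[nm] <- stats[wanted]
    }
    ac_by_site[site] <- activity_counts(ss$a_M, rec$fs)
  }

  fs <- window$signals[[1]]$fs
  ankles <- c(resolve_site("DA", hand), resolve_site("NDA", hand))
  if (all(ankles %in% names(series))) {
    steps <- lapply(ankles, function(s) detect_steps(window$signals[[s]]$gyro[, 3], fs))
    n_steps <- sum(lengths(steps))
    out["STEPS"] <- n_steps
    out["DIST"] <- walk_distance(n_steps, step_length(subject))
    out["STRIDE_VAR"] <- stride_time_variance(steps)
  }

  lat <- function(code_d, code_nd) {
    a <- ac_by_site[resolve_site(code_d, hand)]
    b <- ac_by_site[resolve_site(code_nd, hand)]
    if (is.na(a) || is.na(b)) NA_real_ else laterality_index(a, b)
  }
  out["LAT_upper"] <- lat("DW", "NDW")
  out["LAT_lower_ankle"] <- lat("DA", "NDA")
  out["LAT_feet"] <- lat("DF", "NDF")
  up <- ac_by_site[c("wrist_L", "wrist_R")]
  lo <- ac_by_site[c("ankle_L", "ankle_R")]
  out["LAT_upper_vs_lower"] <- if (anyNA(c(up, lo))) NA_real_ else
    laterality_index(sum(up), sum(lo))

  corr_pair <- function(left, right) {
    if (is.null(series[[left]]) || is.null(series[[right]])) return(NA_real_)
    cross_correlation_feature(series[[left]]$a_M, series[[right]]$a_M, fs)
  }
  out["CORR_wrists"] <- corr_pair("wrist_L", "wrist_R")
  out["CORR_ankles"] <- corr_pair("ankle_L", "ankle_R")
  out["CORR_feet"] <- corr_pair("foot_L", "foot_R")

  if (!is.null(series[["chest"]])) {
    out["ALT_CHANGE"] <- altitude_change(series[["chest"]]$H)
  }
  out["AC_total"] <- if (anyNA(ac_by_site)) NA_real_ else sum(ac_by_site)

  out["age"] <- subject$age
  out["sex"] <- as.numeric(subject$sex == "male")
  out["weight"] <- subject$weight
  out["height"] <- subject$height
  out["bmi"] <- subject$weight / subject$height^2
  out["handedness"] <- as.numeric(subject$handedness == "right")
  out["sport_hours_per_week"] <- subject$sport_hours_per_week
  out[SCORE_NAMES] <- subject$scores[SCORE_NAMES]
  out
}

#' Assemble the per-window feature table of a dataset
#'
#' One row per window over the requested feature bank, prefixed with the
#' window labels. When `include_ree = TRUE` the subject's estimated resting
#' EE is appended as feature `REE` (EE models only; the activity-class gate
#' never sees it).
#'
#' @param dataset a [session_dataset()] (windows should already be gated for
#'   model fitting).
#' @param bank feature names to keep (default: the full [feature_bank()]).
#' @param include_ree append the `REE` column (default FALSE).
#' @param cfg preprocessing configuration.
#' @return a `data.frame` of class `feature_table` with label columns
#'   `subject_id`, `activity_name`, `activity_class`, `window_index`,
#'   `ee_meas`, followed by the features.
#' @export
assemble_feature_table <- function(dataset, bank = feature_bank(),
                                   include_ree = FALSE,
                                   cfg = preprocess_config()) {
  known <- c(feature_bank(), "REE")
  bad <- setdiff(bank, known)
  if (length(bad)) {
    stop_iscee(paste("unknown feature name(s):", paste(bad, collapse = ", ")),
               "iscee_config_error")
  }
  rows <- lapply(dataset$windows, function(w) {
    subj <- dataset$subjects[[w$subject_id]]
    fv <- window_features(w, subj, cfg)[setdiff(bank, "REE")]
    if (include_ree || "REE" %in% bank) fv <- c(fv, REE = subj$ree_est)
    fv
  })
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    subject_id = vapply(dataset$windows, `[[`, "", "subject_id"),
    activity_name = vapply(dataset$windows, `[[`, "", "activity_name"),
    activity_class = vapply(dataset$windows, `[[`, "", "activity_class"),
    window_index = vapply(dataset$windows, `[[`, 0L, "window_index"),
    ee_meas = vapply(dataset$windows, `[[`, 0, "ee_meas"),
    stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(feats, check.names = FALSE))
  class(out) <- c("feature_table", "data.frame")
  out
}

# Label columns of a feature table (everything else is a feature).
META_COLUMNS <- c("subject_id", "activity_name", "activity_class",
                  "window_index", "ee_meas")

#' Published feature presets
#'
#' Named feature sets of the shipped estimation models: the five-feature
#' activity-class gate, the direct regression models and the four
#' class-conditional sets (with the hidden-layer sizes of the neural-network
#' variants).
#'
#' @param name preset name; one of `"classifier"`, `"mlr_direct"`,
#'   `"ann_direct"`, `"mlr_sedentary"`, `"mlr_low_intensity"`,
#'   `"mlr_high_intensity"`, `"mlr_walking"`, `"ann_sedentary"`,
#'   `"ann_low_intensity"`, `"ann_high_intensity"`, `"ann_walking"`.
#' @return list with elements `features` (character) and, for neural-network
#'   presets, `hidden_units`.
#' @export
feature_preset <- function(name) {
  presets <- list(
    classifier = list(features = c("PERC_95(w_Z_DA)", "IQR(w_Z_DA)",
                                   "PERC_99(w_M_Ch)", "PERC_25(w_M_NDW)",
                                   "SD(H_NDW)")),
    mlr_direct = list(features = c("REE", "MEAN(a_M_DW)", "PERC_1(a_M_Ch)",
                                   "MEAN(w_M_DW)", "VAR(H_Ch)",
                                   "PERC_25(a_M_DA)", "VAR(a_M_NDF)")),
    ann_direct = list(features = c("REE", "MEAN(a_M_Ch)", "MEDIAN(w_Z_DA)",
                                   "PERC_25(a_M_DW)", "VAR(w_M_DF)"),
                      hidden_units = 6L),
    mlr_sedentary = list(features = c("REE", "PERC_25(w_M_Ch)", "AC(a_M_NDF)",
                                      "LAT_feet")),
    mlr_low_intensity = list(features = c("REE", "SD(H_NDW)", "PERC_75(a_M_Hi)",
                                          "VAR(H_DF)", "LAT_feet")),
    mlr_high_intensity = list(features = c("REE", "PERC_3(w_M_NDW)", "SD(H_NDW)",
                                           "PERC_5(a_M_Ch)", "RMS(a_M_DA)",
                                           "PERC_1(a_M_DF)")),
    mlr_walking = list(features = c("REE", "weight", "MEDIAN(a_M_Ch)",
                                    "PERC_1(w_M_Hi)", "IQR(a_M_NDF)",
                                    "MEDIAN(w_M_NDF)")),
    ann_sedentary = list(features = c("REE", "PERC_25(w_M_Ch)", "SD(H_Ch)",
                                      "PERC_3(a_M_DF)"), hidden_units = 3L),
    ann_low_intensity = list(features = c("REE", "VAR(H_Ch)", "AC(a_M_Hi)"),
                             hidden_units = 3L),
    ann_high_intensity = list(features = c("REE", "PERC_1(a_M_Ch)", "VAR(H_Ch)",
                                           "RMS(a_M_DA)", "CORR_feet"),
                              hidden_units = 3L),
    ann_walking = list(features = c("REE", "weight", "PERC_25(a_M_Ch)",
                                    "VAR(w_M_Hi)", "IQR(w_M_Hi)"),
                       hidden_units = 3L))
  if (!name %in% names(presets)) {
    stop_iscee(sprintf("unknown preset '%s'", name), "iscee_config_error")
  }
  presets[[name]]
}
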