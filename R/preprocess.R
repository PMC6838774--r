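# Signal conditioning and windowing: Butterworth filters, magnitudes,
# one-minute segmentation, resting-EE extraction and window gating.

#' Default preprocessing configuration
#'
#' Acceleration is high-pass filtered at 0.25 Hz (2nd-order Butterworth) to
#' remove the gravity component; altitude is low-pass filtered at 0.2 Hz to
#' suppress barometric noise; gyroscope channels are left unfiltered.
#' Analysis windows are 60 s, taken from minute 4-8 of each activity; the
#' resting EE is averaged over minute 14-18 of the resting measurement.
#'
#' @return named list of configuration values.
#' @export
preprocess_config <- function() {
  list(accel_highpass_hz = 0.25, altitude_lowpass_hz = 0.2,
       window_seconds = 60, window_minute_range = c(4, 8),
       ree_minute_range = c(14, 18))
}

#' Specify a Butterworth filter
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param order filter order (>= 1); the pipeline default is 2.
#' @param cutoff cutoff frequency in Hz; must lie below the Nyquist rate.
#' @param zero_phase apply forward-backward for zero net phase (default TRUE;
#'   the analysis is offline, so zero-phase filtering costs nothing and keeps
#'   features aligned with the raw streams).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass"), order = 2, cutoff,
                        zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (order < 1) stop_iscee("filter order must be >= 1", "iscee_parameter_error")
  if (cutoff <= 0) stop_iscee("cutoff must be > 0", "iscee_parameter_error")
  structure(list(kind = kind, order = as.integer(order),
                 cutoff = as.numeric(cutoff), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

.butter_cache <- new.env(parent = emptyenv())

butter_coef <- function(order, w, type) {
  key <- sprintf("%d|%.12g|%s", order, w, type)
  hit <- .butter_cache[[key]]
  if (is.null(hit)) {
    bt <- signal::butter(order, w, type = type)
    hit <- list(b = as.numeric(bt$b), a = as.numeric(bt$a))
    .butter_cache[[key]] <- hit
  }
  hit
}

# Direct-form IIR filter via the C filters in stats (columnwise on
# matrices): moving-average part by one-sided convolution (zero initial
# conditions), recursive part by the AR filter. Assumes a[1] == 1 (true for
# signal::butter output).
iir_filter <- function(b, a, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  # moving-average part inline (few taps, vectorised over rows)
  v <- b[1] * x
  for (j in seq_along(b)[-1]) {
    v[j:n, ] <- v[j:n, ] + b[j] * x[1:(n - j + 1), , drop = FALSE]
  }
  if (length(a) > 1) {
    v <- matrix(stats::filter(v, -a[-1], method = "recursive"), n, ncol(x))
  }
  v
}

# Zero-phase (forward-backward) filtering with reflective end padding to
# suppress edge transients. The pad length is sized from the slowest pole's
# decay so the zero-initial-condition transient dies inside the pad.
zero_phase_filter <- function(b, a, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  pad <- 3 * (max(length(a), length(b)) - 1)
  if (length(a) > 1) {
    r <- max(Mod(polyroot(rev(a))))
    if (r < 1) pad <- max(pad, ceiling(-12 / log(r)))
  }
  pad <- min(pad, n - 1)
  refl_top <- 2 * matrix(x[1, ], pad, ncol(x), byrow = TRUE) -
    x[(pad + 1):2, , drop = FALSE]
  refl_bot <- 2 * matrix(x[n, ], pad, ncol(x), byrow = TRUE) -
    x[(n - 1):(n - pad), , drop = FALSE]
  xp <- rbind(refl_top, x, refl_bot)
  y <- iir_filter(b, a, xp)
  y <- iir_filter(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[pad + seq_len(n), , drop = FALSE]
}

#' Apply a Butterworth filter to a signal
#'
#' @param x numeric signal vector, or a matrix filtered column by column.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered signal of the same shape.
#' @export
butterworth_filter <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= fs / 2) {
    stop_iscee(sprintf("cutoff %g Hz is not below Nyquist (%g Hz)",
                       spec$cutoff, fs / 2), "iscee_parameter_error")
  }
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n <= 3 * spec$order) {
    stop_iscee("signal too short for the requested filter order",
               "iscee_parameter_error")
  }
  co <- butter_coef(spec$order, spec$cutoff / (fs / 2),
                    if (spec$kind == "highpass") "high" else "low")
  out <- if (spec$zero_phase) {
    zero_phase_filter(co$b, co$a, x)
  } else {
    iir_filter(co$b, co$a, x)
  }
  if (is.matrix(x)) out else as.numeric(out)
}

#' Euclidean magnitude of a tri-axial signal
#'
#' @param xyz n x 3 matrix (or 3-column data frame) of axis samples.
#' @return numeric vector of per-sample Euclidean norms.
#' @export
magnitude <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop_iscee("magnitude() expects 3 channels",
                                  "iscee_format_error")
  sqrt(rowSums(xyz^2))
}

#' Cut an activity recording into labelled one-minute windows
#'
#' Windows tile the half-open minute range `[minute_range[1], minute_range[2])`
#' relative to activity start; each window spans `[t0 + 60*m, t0 + 60*(m+1))`.
#' Activities shorter than the end of the range yield fewer windows and a
#' warning.
#'
#' @param recordings named list of [sensor_recording()] objects covering the
#'   activity (shared clock).
#' @param activity_bounds numeric `c(start, end)` of the activity in seconds.
#' @param subject_id,activity_name,activity_class labels for the produced
#'   windows.
#' @param minute_range half-open minute interval to keep (default `c(4, 8)`,
#'   ensuring EE has reached a steady state).
#' @return list of [activity_window()] objects.
#' @export
segment_activity <- function(recordings, activity_bounds, subject_id,
                             activity_name, activity_class,
                             minute_range = c(4, 8)) {
  t0 <- activity_bounds[1]
  windows <- list()
  for (m in seq(minute_range[1], minute_range[2] - 1)) {
    ws <- t0 + 60 * m
    we <- ws + 60
    if (we > activity_bounds[2] + 1e-9) next
    slices <- lapply(recordings, function(r) {
      keep <- r$t >= ws & r$t < we
      sensor_recording(r$site, r$t[keep], r$acc[keep, , drop = FALSE],
                       r$gyro[keep, , drop = FALSE], r$alt[keep], r$fs)
    })
    windows[[length(windows) + 1L]] <-
      activity_window(subject_id, activity_name, activity_class,
                      window_index = m - minute_range[1], slices)
  }
  expected <- minute_range[2] - minute_range[1]
  if (length(windows) < expected) {
    warning(sprintf("activity '%s' shorter than minute %d: %d of %d windows produced",
                    activity_name, minute_range[2], length(windows), expected))
  }
  windows
}

#' Measured resting EE from a continuous EE series
#'
#' Averages a per-sample EE series (kcal/min) over the half-open minute range
#' and converts to kcal/day.
#'
#' @param ee numeric EE series in kcal/min.
#' @param t timestamps in seconds matching `ee`.
#' @param minute_range half-open minute interval (default `c(14, 18)`).
#' @return resting EE in kcal/day.
#' @export
measured_ree_from_series <- function(ee, t, minute_range = c(14, 18)) {
  keep <- t >= 60 * minute_range[1] & t < 60 * minute_range[2]
  if (!any(keep) || max(t) < 60 * minute_range[2] - 1e-9) {
    stop_iscee("EE series does not cover the resting-measurement minute range",
               "iscee_data_error")
  }
  mean(ee[keep]) * 1440
}

#' Flag steady-state EE windows
#'
#' A reproducible stand-in for visual steady-state screening: a window is
#' steady when the coefficient of variation of its EE samples is below
#' `cv_max` and its mean lies within `step_max` (relative) of the following
#' window's mean (the last window of an activity is compared to its
#' predecessor).
#'
#' @param ee_window_samples list of numeric vectors, the EE samples of
#'   consecutive windows of one activity.
#' @param cv_max maximum within-window coefficient of variation (default 0.15).
#' @param step_max maximum relative difference between consecutive window
#'   means (default 0.20).
#' @return logical vector, one flag per window.
#' @export
steady_state_flags <- function(ee_window_samples, cv_max = 0.15, step_max = 0.20) {
  mu <- vapply(ee_window_samples, mean, 0)
  cv <- vapply(ee_window_samples, function(x) if (mean(x) == 0) Inf else sd(x) / mean(x), 0)
  n <- length(mu)
  vapply(seq_len(n), function(i) {
    nb <- if (i < n) mu[i + 1] else mu[i - 1]
    cv[i] < cv_max && abs(mu[i] - nb) <= step_max * abs(nb)
  }, TRUE)
}

#' Gate windows for model fitting
#'
#' Keeps windows that are complete, in EE steady state and carry a measured
#' EE label; everything else is dropped with an explicit reason.
#'
#' @param windows list of [activity_window()] objects.
#' @param require_sites sites that must be present for a window to count as
#'   complete (default: all eight).
#' @return list with elements `kept` (list of windows) and `dropped`
#'   (data frame of `subject_id`, `activity_name`, `window_index`, `reason`).
#' @export
gate_windows <- function(windows, require_sites = SITES) {
  kept <- list()
  drops <- list()
  for (w in windows) {
    reason <- NULL
    if (!w$complete || !all(require_sites %in% names(w$signals))) {
      reason <- "missing_sensor"
    } else if (is.na(w$ee_meas)) {
      reason <- "missing_ee"
    } else if (!w$steady_state) {
      reason <- "non_steady"
    } else if (isTRUE(w$truth$protocol_violation)) {
      reason <- "protocol_violation"
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1L]] <- w
    } else {
      drops[[length(drops) + 1L]] <-
        data.frame(subject_id = w$subject_id, activity_name = w$activity_name,
                   window_index = w$window_index, reason = reason,
                   stringsAsFactors = FALSE)
    }
  }
  dropped <- if (length(drops)) do.call(rbind, drops) else
    data.frame(subject_id = character(), activity_name = character(),
               window_index = integer(), reason = character())
  list(kept = kept, dropped = dropped)
}
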