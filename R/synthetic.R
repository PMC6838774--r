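# Seeded synthetic-cohort generator: virtual subjects, 8-site IMU/altimeter
# signals per activity window, ground-truth step events and MET-calibrated EE
# labels. Signal morphology is deliberately simple (windowed sinusoids,
# Gaussian pulse trains, impacts, white noise): the generator exercises the
# pipeline and its recovery properties, not biomechanical realism.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a cohort of 30 ambulatory subjects
#' (2:1 male, demographics truncated to the published ranges), 12 activities
#' in four classes with published class MET means, the published
#' speed-cadence mapping, measured REE scattered 10% (relative) around the
#' updated Harris-Benedict prediction and EE labels scattered 10% around the
#' MET-derived value.
#'
#' @param n_subjects cohort size (default 30).
#' @param fs sampling rate in Hz (default 50, the analysis rate).
#' @param seed master seed; every subject and window derives its own
#'   sub-seed from it.
#' @param ee_rel_sd relative SD of the EE label noise (default 0.10).
#' @param ree_rel_sd relative SD of measured REE around the equation value
#'   (default 0.10).
#' @param gait_jitter_sd SD of the per-step timing jitter in seconds
#'   (default 0.02).
#' @param sensor_noise_acc,sensor_noise_gyro,sensor_noise_alt white-noise SDs
#'   of the acceleration (g), angular-velocity (deg/s) and altitude (m)
#'   channels (defaults 0.01, 1, 0.15).
#' @param dropout_rate fraction of windows with an injected missing sensor
#'   (default 0).
#' @param windows_per_activity windows kept per activity (default 4,
#'   minutes 4-8).
#' @return list of class `sim_config`, including the activity menu
#'   (`$activities`) and the speed-cadence table (`$cadence_table`).
#' @export
sim_config <- function(n_subjects = 30, fs = 50, seed = 1,
                       ee_rel_sd = 0.10, ree_rel_sd = 0.10,
                       gait_jitter_sd = 0.02,
                       sensor_noise_acc = 0.01, sensor_noise_gyro = 1,
                       sensor_noise_alt = 0.15,
                       dropout_rate = 0, windows_per_activity = 4) {
  activities <- data.frame(
    name = c("rest", "reading", "games_tablet",
             "riding_elevator", "washing_dishes", "vacuum_cleaning",
             "weight_lifting", "squats", "badminton",
             "walking_1kmh", "walking_4kmh", "climbing_stairs"),
    class = rep(ACTIVITY_CLASSES, each = 3),
    met_mean = c(0.9, 1.1, 1.3, 1.5, 2.4, 3.2, 2.0, 4.2, 6.0, 2.5, 4.2, 7.1),
    met_sd = c(0.2, 0.3, 0.4, 0.3, 0.8, 0.6, 0.6, 1.8, 1.8, 0.5, 1.9, 1.7),
    speed_kmh = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 1, 4, NA),
    cadence = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, 56, 105, 80),
    climb_m_per_min = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 3),
    stringsAsFactors = FALSE)
  cfg <- list(n_subjects = n_subjects, fs = fs, seed = seed,
              ee_rel_sd = ee_rel_sd, ree_rel_sd = ree_rel_sd,
              gait_jitter_sd = gait_jitter_sd,
              sensor_noise_acc = sensor_noise_acc,
              sensor_noise_gyro = sensor_noise_gyro,
              sensor_noise_alt = sensor_noise_alt,
              dropout_rate = dropout_rate,
              windows_per_activity = windows_per_activity,
              activities = activities,
              cadence_table = c(`1` = 56, `2` = 76, `3` = 88, `4` = 105,
                                `5` = 113, `6` = 124))
  stopifnot(all(vapply(cfg[c("ee_rel_sd", "ree_rel_sd", "gait_jitter_sd",
                             "sensor_noise_acc", "sensor_noise_gyro",
                             "sensor_noise_alt")], `>=`, TRUE, 0)),
            all(activities$met_mean > 0.5))
  structure(cfg, class = "sim_config")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= lower && v <= upper) break
    }
    out[i] <- v
  }
  out
}

subject_seed <- function(config, index) {
  (config$seed * 100003 + index * 1009) %% 2147483647
}

window_seed <- function(config, index, act_i, win_i) {
  (config$seed * 100003 + index * 1009 + act_i * 101 + win_i * 7 + 31) %% 2147483647
}

#' Simulate one subject profile
#'
#' Demographics are drawn from truncated normals matching the published
#' cohort (age 54.1 +- 11.9 in 27-72, weight 75.5 +- 16.2 in 44-106, height
#' 1.71 +- 0.09 in 1.48-1.91, 2:1 male); measured REE is the updated
#' Harris-Benedict prediction times `1 + N(0, ree_rel_sd)`.
#'
#' @param config a [sim_config()].
#' @param index subject index (drives the sub-seed).
#' @return a [subject_profile()]; the hidden per-subject movement amplitude
#'   multiplier is attached as attribute `"amp"`.
#' @export
simulate_subject <- function(config, index) {
  set.seed(subject_seed(config, index))
  sex <- if (runif(1) < 2 / 3) "male" else "female"
  age <- rtruncnorm1(1, 54.1, 11.9, 27, 72)
  weight <- rtruncnorm1(1, 75.5, 16.2, 44, 106)
  height <- rtruncnorm1(1, 1.71, 0.09, 1.48, 1.91)
  handed <- if (runif(1) < 0.9) "right" else "left"
  sport <- rtruncnorm1(1, 3.9, 3.6, 0, 14)
  tetra <- runif(1) < 1 / 3
  scores <- c(
    scim_total = rtruncnorm1(1, 85, 10, 40, 100),
    scim_mobility = rtruncnorm1(1, 28.1, 3.9, 15, 30),
    scim_selfcare = rtruncnorm1(1, 18, 2, 10, 20),
    scim_respiration = rtruncnorm1(1, 35, 5, 20, 40),
    six_mwt_m = rtruncnorm1(1, 486, 158, 137, 744),
    ten_mwt_s = rtruncnorm1(1, 10, 4, 5, 30),
    tug_s = rtruncnorm1(1, 12, 5, 6, 40),
    grassp_total = rtruncnorm1(1, 85, 12, 40, 96),
    grassp_strength = rtruncnorm1(1, 45, 6, 20, 50),
    grassp_sensibility = rtruncnorm1(1, 20, 3, 10, 24),
    ais = sample(c(2, 3, 4), 1, prob = c(1, 1, 28)),
    nli = if (tetra) sample(1:8, 1) else sample(9:20, 1))
  subj <- subject_profile(id = sprintf("S%02d", index), age = age, sex = sex,
                          weight = weight, height = height, handedness = handed,
                          sport_hours_per_week = sport, scores = scores)
  subj$ree_est <- estimate_ree(subj, "updated_harris_benedict")
  repeat {
    ree_meas <- subj$ree_est * (1 + rnorm(1, 0, config$ree_rel_sd))
    if (ree_meas > 0) break
  }
  subj$ree_meas <- ree_meas
  attr(subj, "amp") <- exp(rnorm(1, 0, 0.2))
  subj
}

gauss_pulses <- function(t, centers, width, amps) {
  amps <- rep(amps, length.out = length(centers))
  out <- numeric(length(t))
  for (i in seq_along(centers)) {
    out <- out + amps[i] * exp(-((t - centers[i])^2) / (2 * width^2))
  }
  out
}

slow_wiggle <- function(t, amp, f_lo = 0.3, f_hi = 1.5, n_comp = 3) {
  out <- numeric(length(t))
  for (i in seq_len(n_comp)) {
    out <- out + sin(2 * pi * runif(1, f_lo, f_hi) * t + runif(1, 0, 2 * pi))
  }
  amp * out / n_comp
}

# Intermittent on/off envelope for low-intensity activities: bouts of 2-5 s
# of movement separated by 5-10 s pauses (~30% duty cycle).
duty_envelope <- function(t) {
  env <- numeric(length(t))
  pos <- runif(1, 0, 3)
  while (pos < max(t)) {
    on <- runif(1, 2, 5)
    env[t >= pos & t < pos + on] <- 1
    pos <- pos + on + runif(1, 5, 10)
  }
  env
}

site_base_alt <- c(wrist_L = 1.0, wrist_R = 1.0, ankle_L = 0.15, ankle_R = 0.15,
                   foot_L = 0.05, foot_R = 0.05, chest = 1.4, hip = 1.0)

#' Simulate one labelled activity window
#'
#' Class-specific signal generators: walking produces anti-phase per-ankle
#' sagittal gyroscope pulse trains at the activity's cadence (with timing
#' jitter), foot-strike impacts, arm-swing wrist oscillation, chest bounce at
#' step frequency and (for stair climbing) an altitude ramp; the sedentary
#' class produces low-amplitude slow wiggles; the low-intensity class
#' intermittent upper-limb movement; the high-intensity class sustained
#' multi-site movement. All amplitudes scale with the drawn MET, so EE is
#' recoverable from the signals. The measured-EE label is the MET draw
#' converted by the shared MET constants and scattered by `ee_rel_sd`.
#'
#' @param subject a [simulate_subject()] result.
#' @param activity one row of `config$activities` (or an activity name).
#' @param config a [sim_config()].
#' @param seed seed for this window.
#' @param window_index index within the activity.
#' @return an [activity_window()] with ground truth (MET draw, step event
#'   times per leg, cadence) in `$truth`.
#' @export
simulate_activity_window <- function(subject, activity, config, seed,
                                     window_index = 0) {
  if (is.character(activity)) {
    hit <- config$activities[config$activities$name == activity, , drop = FALSE]
    if (!nrow(hit)) stop_iscee(sprintf("unknown activity '%s'", activity),
                               "iscee_config_error")
    activity <- hit
  }
  set.seed(seed)
  fs <- config$fs
  n <- 60 * fs
  t <- (seq_len(n) - 1) / fs
  amp <- attr(subject, "amp") %||% 1
  met <- rtruncnorm1(1, activity$met_mean, activity$met_sd,
                     max(0.5, activity$met_mean - 2.5 * activity$met_sd),
                     activity$met_mean + 2.5 * activity$met_sd)
  repeat {
    ee_meas <- ee_from_met(met, subject$weight) * (1 + rnorm(1, 0, config$ee_rel_sd))
    if (ee_meas > 0) break
  }
  cls <- activity$class
  intens <- amp * max(met - 0.8, 0.1)

  sig <- list()  # per site: list(acc=n x 3, gyro=n x 3, alt=n)
  blank <- function() list(acc = matrix(0, n, 3), gyro = matrix(0, n, 3),
                           alt = numeric(n))
  for (s in SITES) sig[[s]] <- blank()
  truth <- list(met = met, class = cls, steps_L = numeric(), steps_R = numeric(),
                cadence = NA_real_)

  if (cls == "sedentary") {
    for (s in SITES) {
      for (ax in 1:3) {
        sig[[s]]$acc[, ax] <- slow_wiggle(t, 0.004 * intens)
        sig[[s]]$gyro[, ax] <- slow_wiggle(t, 1.2 * intens)
      }
    }
  } else if (cls == "low_intensity") {
    env <- duty_envelope(t)
    for (s in c("wrist_L", "wrist_R")) {
      for (ax in 1:3) {
        sig[[s]]$acc[, ax] <- env * slow_wiggle(t, 0.03 + 0.02 * intens)
        sig[[s]]$gyro[, ax] <- env * slow_wiggle(t, 12 + 10 * intens, 0.5, 2.5)
      }
      # slow vertical arm excursions survive the 0.2 Hz altitude low-pass
      sig[[s]]$alt <- (0.10 + 0.06 * intens) * sin(2 * pi * 0.08 * t + runif(1, 0, 2 * pi))
    }
    for (s in c("chest", "hip")) {
      for (ax in 1:3) {
        sig[[s]]$acc[, ax] <- env * slow_wiggle(t, 0.01 + 0.008 * intens)
        sig[[s]]$gyro[, ax] <- env * slow_wiggle(t, 2 + 2 * intens)
      }
      sig[[s]]$alt <- (0.02 + 0.015 * intens) * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi))
    }
    for (s in c("ankle_L", "ankle_R", "foot_L", "foot_R")) {
      for (ax in 1:3) {
        sig[[s]]$acc[, ax] <- slow_wiggle(t, 0.004 + 0.004 * intens)
        sig[[s]]$gyro[, ax] <- slow_wiggle(t, 1.5 + 1.2 * intens)
      }
      sig[[s]]$alt <- (0.015 + 0.012 * intens) * sin(2 * pi * 0.09 * t + runif(1, 0, 2 * pi))
    }
  } else if (cls == "high_intensity") {
    for (s in c("wrist_L", "wrist_R")) {
      for (ax in 1:3) {
        sig[[s]]$acc[, ax] <- slow_wiggle(t, 0.06 + 0.04 * intens, 0.8, 3)
        sig[[s]]$gyro[, ax] <- slow_wiggle(t, 25 + 12 * intens, 0.8, 3)
      }
      sig[[s]]$alt <- (0.08 + 0.05 * intens) * sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi))
    }
    for (s in c("chest", "hip")) {
      for (ax in 1:3) {
        sig[[s]]$acc[, ax] <- slow_wiggle(t, 0.03 + 0.02 * intens, 0.8, 3)
        sig[[s]]$gyro[, ax] <- slow_wiggle(t, 12 + 8 * intens, 0.8, 3)
      }
      sig[[s]]$alt <- (0.04 + 0.03 * intens) * sin(2 * pi * 0.12 * t + runif(1, 0, 2 * pi))
    }
    for (s in c("ankle_L", "ankle_R", "foot_L", "foot_R")) {
      for (ax in 1:3) {
        sig[[s]]$acc[, ax] <- slow_wiggle(t, 0.02 + 0.012 * intens, 0.8, 3)
        sig[[s]]$gyro[, ax] <- slow_wiggle(t, 8 + 4 * intens, 0.8, 3)
      }
    }
  } else { # walking
    cad <- activity$cadence
    truth$cadence <- cad
    per_leg <- 120 / cad  # seconds between steps of the same leg
    mk_events <- function(offset) {
      ev <- offset
      while (ev[length(ev)] + per_leg < 60.05) {
        ev <- c(ev, ev[length(ev)] + per_leg + rnorm(1, 0, config$gait_jitter_sd))
      }
      ev[ev >= 0.05 & ev <= 59.95]
    }
    ev_L <- mk_events(runif(1, 0.05, 0.05 + per_leg))
    ev_R <- mk_events(ev_L[1] - per_leg / 2)
    truth$steps_L <- ev_L
    truth$steps_R <- ev_R
    g_amp <- 150 + 15 * intens
    a_amp <- 0.3 + 0.08 * intens
    for (side in c("L", "R")) {
      ev <- if (side == "L") ev_L else ev_R
      ankle <- paste0("ankle_", side); foot <- paste0("foot_", side)
      amps <- g_amp * (1 + 0.05 * rnorm(length(ev)))
      sig[[ankle]]$gyro[, 3] <- gauss_pulses(t, ev, 0.07, amps)
      sig[[ankle]]$gyro[, 1] <- gauss_pulses(t, ev, 0.09, 0.25 * amps)
      sig[[ankle]]$acc[, 1] <- gauss_pulses(t, ev, 0.05, a_amp * (1 + 0.1 * rnorm(length(ev))))
      sig[[foot]]$gyro[, 3] <- gauss_pulses(t, ev, 0.06, 0.8 * amps)
      sig[[foot]]$acc[, 1] <- gauss_pulses(t, ev, 0.03,
                                           1.6 * a_amp * (1 + 0.1 * rnorm(length(ev))))
      sig[[foot]]$acc[, 3] <- gauss_pulses(t, ev, 0.05, 0.8 * a_amp)
    }
    f_stride <- cad / 120
    f_step <- cad / 60
    for (side in c("L", "R")) {
      wr <- paste0("wrist_", side)
      ph <- if (side == "L") 0 else pi
      sig[[wr]]$gyro[, 2] <- (25 + 5 * intens) * sin(2 * pi * f_stride * t + ph)
      sig[[wr]]$acc[, 1] <- (0.04 + 0.015 * intens) * sin(2 * pi * f_stride * t + ph)
    }
    sig$chest$acc[, 3] <- (0.04 + 0.015 * intens) * sin(2 * pi * f_step * t)
    sig$chest$gyro[, 1] <- (4 + 1.5 * intens) * sin(2 * pi * f_step * t + 0.4)
    sig$hip$acc[, 3] <- (0.05 + 0.02 * intens) * sin(2 * pi * f_step * t + 0.2)
    sig$hip$gyro[, 3] <- (6 + 2 * intens) * sin(2 * pi * f_step * t + 0.8)
    if (activity$climb_m_per_min > 0) {
      for (s in SITES) sig[[s]]$alt <- sig[[s]]$alt + activity$climb_m_per_min * t / 60
    }
  }

  recordings <- lapply(SITES, function(s) {
    acc <- sig[[s]]$acc + matrix(rnorm(3 * n, 0, config$sensor_noise_acc), n, 3)
    acc[, 3] <- acc[, 3] + 1  # gravity
    gyro <- sig[[s]]$gyro + matrix(rnorm(3 * n, 0, config$sensor_noise_gyro), n, 3)
    alt <- site_base_alt[[s]] + sig[[s]]$alt + rnorm(n, 0, config$sensor_noise_alt)
    sensor_recording(s, t, acc, gyro, alt, fs)
  })
  activity_window(subject$id, activity$name, cls, window_index, recordings,
                  ee_meas = ee_meas, truth = truth)
}

#' Simulate a full cohort session
#'
#' `n_subjects x 12 activities x windows_per_activity` labelled windows with
#' consistent class labels and ground truth. With `dropout_rate > 0`, a
#' matching fraction of windows loses one random sensor and is flagged
#' incomplete, to exercise the gating stage.
#'
#' @param config a [sim_config()].
#' @return a [session_dataset()]; fixed seed gives a byte-identical dataset.
#' @export
simulate_cohort <- function(config = sim_config()) {
  subjects <- lapply(seq_len(config$n_subjects), simulate_subject, config = config)
  windows <- list()
  for (i in seq_len(config$n_subjects)) {
    for (a in seq_len(nrow(config$activities))) {
      for (w in seq_len(config$windows_per_activity)) {
        win <- simulate_activity_window(subjects[[i]], config$activities[a, ],
                                        config, window_seed(config, i, a, w),
                                        window_index = w - 1)
        if (config$dropout_rate > 0 && runif(1) < config$dropout_rate) {
          drop_site <- sample(SITES, 1)
          win$signals[[drop_site]] <- NULL
          win$complete <- FALSE
        }
        windows[[length(windows) + 1L]] <- win
      }
    }
  }
  session_dataset(subjects, windows)
}

#' Simulate a cohort and return its feature table directly
#'
#' Streaming variant of [simulate_cohort()] + [assemble_feature_table()]:
#' windows are generated, featurised and discarded one at a time, so large
#' cohorts never hold all raw signals in memory. Identical sub-seeding makes
#' the rows match the non-streaming path.
#'
#' @param config a [sim_config()].
#' @param bank feature names to compute (default: full bank).
#' @param include_ree append the `REE` feature (default TRUE).
#' @return list with `features` (feature table, plus `truth_met` and
#'   `truth_steps` columns) and `subjects`.
#' @export
simulate_feature_cohort <- function(config = sim_config(), bank = feature_bank(),
                                    include_ree = TRUE) {
  subjects <- lapply(seq_len(config$n_subjects), simulate_subject, config = config)
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    for (a in seq_len(nrow(config$activities))) {
      for (w in seq_len(config$windows_per_activity)) {
        win <- simulate_activity_window(subjects[[i]], config$activities[a, ],
                                        config, window_seed(config, i, a, w),
                                        window_index = w - 1)
        fv <- window_features(win, subjects[[i]])[setdiff(bank, "REE")]
        if (include_ree) fv <- c(fv, REE = subjects[[i]]$ree_est)
        rows[[length(rows) + 1L]] <- c(
          list(subject_id = win$subject_id, activity_name = win$activity_name,
               activity_class = win$activity_class,
               window_index = win$window_index, ee_meas = win$ee_meas,
               truth_met = win$truth$met,
               truth_steps = length(win$truth$steps_L) + length(win$truth$steps_R)),
          as.list(fv))
      }
    }
  }
  feats <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  class(feats) <- c("feature_table", "data.frame")
  names(subjects) <- vapply(subjects, `[[`, "", "id")
  list(features = feats, subjects = subjects)
}
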