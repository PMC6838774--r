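# Translation of institutional physical-activity guidelines into daily step
# and minute goals from per-speed energy cost, cadence and daily EE.

#' Cohort walking-speed profiles
#'
#' The per-speed inputs of the guideline translation: cadence (steps/min),
#' average resting EE and average measured EE during walking at that speed
#' (kcal/day), and the energy cost of 30 minutes of walking (kcal). For the
#' numeric moderate speeds (3-6 km/h) the cohort's published 30-min cost is
#' carried as-is; for 1 and 2 km/h and the average profiles it is derived
#' from the daily additional EE as `(measured - ree)/1440 * 30`, the
#' unrounded quantity behind the published minute goals for those rows
#' (their displayed per-bout energies are rounded). The
#' `"average_moderate"` profile averages
#' the moderate speeds (3-6 km/h, nominal 4.3 km/h) and `"average_all"` all
#' speeds (nominal 3.3 km/h).
#'
#' @return data frame of class `speed_profiles` with columns `speed`
#'   (km/h or the average labels), `ee_per_30min`, `cadence`, `ree`,
#'   `measured_ee`.
#' @export
speed_profiles <- function() {
  df <- data.frame(
    speed = c("1", "2", "3", "4", "5", "6", "average_moderate", "average_all"),
    ee_per_30min = c(NA, NA, 84, 141, 127, 160, NA, NA),
    cadence = c(56, 76, 88, 105, 113, 124, 104, 91),
    ree = c(1477, 1661, 1557, 1814, 1653, 1895, 1685, 1641),
    measured_ee = c(3971, 4894, 5579, 8566, 7737, 9859, 7422, 6359),
    stringsAsFactors = FALSE)
  miss <- is.na(df$ee_per_30min)
  df$ee_per_30min[miss] <- (df$measured_ee[miss] - df$ree[miss]) / 1440 * 30
  class(df) <- c("speed_profiles", "data.frame")
  df
}

get_profile <- function(profiles, speed) {
  row <- profiles[profiles$speed == as.character(speed), , drop = FALSE]
  if (nrow(row) != 1) {
    stop_iscee(sprintf("no speed profile for '%s'", speed), "iscee_config_error")
  }
  row
}

#' Minutes of walking needed for a target energy expenditure
#'
#' `round(target / ee_per_30min * 30)` to the nearest whole minute (half away
#' from zero); the unrounded value is linear in the target and inversely
#' proportional to the per-30-min energy cost.
#'
#' @param target_kcal target additional EE in kcal (> 0).
#' @param profile one row of [speed_profiles()].
#' @return integer minutes.
#' @export
minutes_for_energy <- function(target_kcal, profile) {
  stopifnot(target_kcal > 0)
  round_half_up(target_kcal / profile$ee_per_30min * 30)
}

#' Step goal for a walking duration
#'
#' @param minutes walking duration (min).
#' @param cadence steps per minute.
#' @return integer steps, `round(minutes * cadence)` half away from zero.
#' @export
steps_for_minutes <- function(minutes, cadence) {
  stopifnot(minutes >= 0, cadence >= 0)
  round_half_up(minutes * cadence)
}

#' Daily EE attributable to the activity
#'
#' @param profile one row of [speed_profiles()].
#' @return `measured_ee - ree` in kcal/day.
#' @export
additional_daily_ee <- function(profile) {
  d <- profile$measured_ee - profile$ree
  if (any(d < 0)) stop_iscee("measured EE below resting EE", "iscee_data_error")
  d
}

#' Guideline presets of the translation table
#'
#' @return data frame naming each shipped guideline, its calculation basis
#'   (`"minutes"` or `"kcal"`), basis value and the speeds it is evaluated
#'   at.
#' @export
guideline_presets <- function() {
  data.frame(
    guideline = c("30min_moderate_pa", "75kcal_moderate_pa",
                  "60min_moderate_pa", "150kcal_moderate_pa",
                  "10000_steps_benchmark", "300kcal_10000_steps",
                  "569kcal_1000min_week"),
    basis = c("minutes", "kcal", "minutes", "kcal", "steps", "kcal", "kcal"),
    value = c(30, 75, 60, 150, 10000, 300, 569),
    speeds = c("3,4,5,6,average_moderate", "3,4,5,6,average_moderate",
               "average_moderate", "average_moderate",
               "average_all", "1,2,3,4,5,6,average_all", "average_moderate"),
    stringsAsFactors = FALSE)
}

#' Translate activity guidelines into daily step goals
#'
#' Reproduces the guideline-translation calculus: a minutes basis fixes the
#' daily walking time and derives the step goal and energy; a kcal basis
#' derives the required minutes from the per-speed energy cost first. Step
#' goals are computed from the unrounded minutes (rounding is applied once,
#' at output).
#'
#' @param presets guideline presets (default [guideline_presets()]).
#' @param profiles speed profiles (default [speed_profiles()]).
#' @return data frame of class `recommendation_table`: one row per
#'   (guideline, speed) with goal minutes, goal steps, cadence, resting,
#'   measured and additional daily EE, and the energy of the prescribed
#'   bout.
#' @export
build_translation_table <- function(presets = guideline_presets(),
                                    profiles = speed_profiles()) {
  rows <- list()
  for (i in seq_len(nrow(presets))) {
    p <- presets[i, ]
    for (sp in strsplit(p$speeds, ",", fixed = TRUE)[[1]]) {
      pr <- get_profile(profiles, sp)
      if (p$basis == "minutes") {
        mins <- p$value
        steps <- steps_for_minutes(mins, pr$cadence)
        bout_kcal <- round_half_up(pr$ee_per_30min * mins / 30)
        goal_min <- mins
      } else if (p$basis == "kcal") {
        raw_min <- p$value / pr$ee_per_30min * 30
        goal_min <- round_half_up(raw_min)
        steps <- round_half_up(raw_min * pr$cadence)
        bout_kcal <- p$value
      } else { # steps benchmark
        raw_min <- p$value / pr$cadence
        goal_min <- round_half_up(raw_min)
        steps <- p$value
        bout_kcal <- round_half_up(raw_min * pr$ee_per_30min / 30)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        guideline = p$guideline, basis = p$basis, basis_value = p$value,
        speed = sp, goal_minutes = goal_min, goal_steps = steps,
        bout_kcal = bout_kcal, cadence = pr$cadence, ree = pr$ree,
        measured_ee = pr$measured_ee,
        additional_ee = additional_daily_ee(pr), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recommendation_table", "data.frame")
  out
}
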