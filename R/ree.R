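# Resting energy expenditure (REE) prediction equations. Coefficients are
# data, transcribed once from the primary sources and locked by tests.

KCAL_PER_MJ <- 239.006

#' REE equation coefficient tables
#'
#' Closed-form REE prediction equations for the non-disabled population.
#' `harris_benedict` and `updated_harris_benedict` take weight (kg), height
#' (cm) and age (years); `mifflin_st_jeor` likewise with a sex offset;
#' `mueller` is MJ/day-native in weight, sex and age (converted at
#' 239.006 kcal/MJ). The BMI-dependent Mueller variant ships without
#' coefficients (its class-specific table lives in the primary source only)
#' and must be configured by the user.
#'
#' @return nested list of coefficients with provenance strings.
#' @export
ree_constants <- function() {
  list(
    harris_benedict = list(
      source = "Harris & Benedict (1919), PNAS 4:370-373",
      male = c(intercept = 66.5, weight = 13.75, height_cm = 5.003, age = -6.755),
      female = c(intercept = 655.1, weight = 9.563, height_cm = 1.850, age = -4.676)),
    updated_harris_benedict = list(
      source = "Roza & Shizgal (1984), Am J Clin Nutr 40:168-182",
      male = c(intercept = 88.362, weight = 13.397, height_cm = 4.799, age = -5.677),
      female = c(intercept = 447.593, weight = 9.247, height_cm = 3.098, age = -4.330)),
    mifflin_st_jeor = list(
      source = "Mifflin et al. (1990), Am J Clin Nutr 51:241-247",
      male = c(intercept = 5, weight = 10, height_cm = 6.25, age = -5),
      female = c(intercept = -161, weight = 10, height_cm = 6.25, age = -5)),
    mueller = list(
      source = "Mueller et al. (2004), Am J Clin Nutr 80:1379-1390; MJ/day",
      mj = c(intercept = 3.21, weight = 0.047, sex_male = 1.009, age = -0.01452)),
    mueller_bmi = list(
      source = "BMI-class coefficients not shipped; supply via `coefficients`",
      mj = NULL))
}

#' REE model identifiers
#' @return character vector of supported model ids; the first entry,
#'   `updated_harris_benedict`, is the pipeline default.
#' @export
ree_models <- function() {
  c("updated_harris_benedict", "harris_benedict", "mifflin_st_jeor",
    "mueller", "mueller_bmi")
}

#' Estimate resting energy expenditure
#'
#' @param subject a [subject_profile()] (uses age, sex, weight, height).
#' @param model one of [ree_models()]; default `"updated_harris_benedict"`.
#' @param coefficients optional replacement coefficient table (required for
#'   `"mueller_bmi"`): a function `f(subject)` returning kcal/day.
#' @return REE in kcal/day.
#' @export
estimate_ree <- function(subject, model = "updated_harris_benedict",
                         coefficients = NULL) {
  model <- match.arg(model, ree_models())
  h_cm <- subject$height * 100
  k <- ree_constants()[[model]]
  if (model %in% c("harris_benedict", "updated_harris_benedict",
                   "mifflin_st_jeor")) {
    co <- k[[subject$sex]]
    co[["intercept"]] + co[["weight"]] * subject$weight +
      co[["height_cm"]] * h_cm + co[["age"]] * subject$age
  } else if (model == "mueller") {
    co <- k$mj
    mj <- co[["intercept"]] + co[["weight"]] * subject$weight +
      co[["sex_male"]] * (subject$sex == "male") + co[["age"]] * subject$age
    mj * KCAL_PER_MJ
  } else {
    if (is.null(coefficients)) {
      stop_iscee(paste("mueller_bmi is not configured: supply its BMI-class",
                       "coefficient table via `coefficients`"),
                 "iscee_not_configured_error")
    }
    coefficients(subject)
  }
}

#' Evaluate REE prediction equations against measured REE
#'
#' For each model, per-subject percentage errors are computed against the
#' measured REE and summarised as mean absolute error (MAE, % and kcal/day),
#' mean signed error (MSE) and maximum error, overall and within subgroups
#' (sex; paraparetic vs tetraparetic when a numeric `nli` score marks
#' cervical levels).
#'
#' @param subjects list of [subject_profile()] objects with `ree_meas` set.
#' @param models model ids to evaluate (default: all configured equations).
#' @param tetra_ids optional character vector of subject ids counted as
#'   tetraparetic for the subgroup summary.
#' @return data frame, one row per model and subgroup.
#' @export
evaluate_ree_models <- function(subjects, models = setdiff(ree_models(), "mueller_bmi"),
                                tetra_ids = character()) {
  subjects <- Filter(function(s) !is.na(s$ree_meas), subjects)
  if (!length(subjects)) stop_iscee("no subjects with measured REE", "iscee_data_error")
  rows <- list()
  for (m in models) {
    pred <- vapply(subjects, estimate_ree, 0, model = m)
    meas <- vapply(subjects, `[[`, 0, "ree_meas")
    ids <- vapply(subjects, `[[`, "", "id")
    sexes <- vapply(subjects, `[[`, "", "sex")
    err_pct <- (pred - meas) / meas * 100
    err_kcal <- pred - meas
    grp <- list(overall = rep(TRUE, length(pred)),
                male = sexes == "male", female = sexes == "female",
                tetraparetic = ids %in% tetra_ids,
                paraparetic = !ids %in% tetra_ids)
    for (g in names(grp)) {
      sel <- grp[[g]]
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, group = g, n = sum(sel),
        mae_pct = mean(abs(err_pct[sel])), mae_kcal = mean(abs(err_kcal[sel])),
        mse_pct = mean(err_pct[sel]), mse_kcal = mean(err_kcal[sel]),
        max_err_pct = max(abs(err_pct[sel])),
        max_err_kcal = max(abs(err_kcal[sel])), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
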