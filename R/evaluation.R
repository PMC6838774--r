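# Performance analysis: error metrics, Bland-Altman agreement, paired
# equivalence (TOST), correlation wrappers and MET conversion.

#' MET conversion constants
#'
#' One metabolic equivalent of task (MET) is an oxygen uptake of
#' 3.5 mL O2 per kg body weight per minute; energy equivalent of oxygen
#' fixed at 4.86 kcal/L (RER-neutral) unless overridden.
#'
#' @param vo2_per_met mL O2 / kg / min per MET.
#' @param kcal_per_l_o2 kcal per litre of oxygen.
#' @return list of the two constants.
#' @export
met_constants <- function(vo2_per_met = 3.5, kcal_per_l_o2 = 4.86) {
  stopifnot(vo2_per_met > 0, kcal_per_l_o2 > 0)
  list(vo2_per_met = vo2_per_met, kcal_per_l_o2 = kcal_per_l_o2)
}

#' Convert EE in kcal/day to MET
#'
#' `VO2 [mL/min] = EE / (1440 * kcal_per_l_o2) * 1000`;
#' `MET = VO2 / (vo2_per_met * weight)`.
#'
#' @param ee energy expenditure in kcal/day.
#' @param weight body weight in kg.
#' @param constants see [met_constants()].
#' @return MET value.
#' @export
met_from_ee <- function(ee, weight, constants = met_constants()) {
  stopifnot(weight > 0)
  vo2 <- ee / (1440 * constants$kcal_per_l_o2) * 1000
  vo2 / (constants$vo2_per_met * weight)
}

#' Convert MET to EE in kcal/day (inverse of [met_from_ee()])
#'
#' @inheritParams met_from_ee
#' @param met MET value.
#' @return EE in kcal/day.
#' @export
ee_from_met <- function(met, weight, constants = met_constants()) {
  met * constants$vo2_per_met * weight / 1000 * constants$kcal_per_l_o2 * 1440
}

#' EE estimation error metrics
#'
#' Per-window percentage errors are `(pred - meas)/meas * 100`. The headline
#' summaries are computed within subject first, then averaged (mean +- SD)
#' across subjects; the maximum error is over all windows. Optional grouping
#' columns produce subgroup breakdowns.
#'
#' @param measured,predicted equal-length vectors; `measured > 0`.
#' @param subject_id subject of each window (used for the across-subject
#'   summary; a single pooled pseudo-subject when omitted).
#' @param groups optional named list of per-window grouping vectors
#'   (e.g. `list(class = ...)`).
#' @return list of class `ee_eval` with elements `overall` (one-row data
#'   frame), `by_group` (data frame per grouping) and the per-window errors.
#' @export
error_metrics <- function(measured, predicted, subject_id = NULL, groups = NULL) {
  stopifnot(length(measured) == length(predicted))
  if (any(measured <= 0)) stop_iscee("measured EE must be > 0", "iscee_data_error")
  if (is.null(subject_id)) subject_id <- rep("all", length(measured))
  err_pct <- (predicted - measured) / measured * 100
  err_kcal <- predicted - measured

  summarise <- function(sel) {
    sid <- subject_id[sel]
    per_subj_mae <- tapply(abs(err_pct[sel]), sid, mean)
    per_subj_mse <- tapply(err_pct[sel], sid, mean)
    per_subj_mae_kcal <- tapply(abs(err_kcal[sel]), sid, mean)
    per_subj_mse_kcal <- tapply(err_kcal[sel], sid, mean)
    data.frame(
      n_windows = sum(sel), n_subjects = length(per_subj_mae),
      mae_pct = mean(per_subj_mae), mae_pct_sd = sd(per_subj_mae),
      mae_kcal = mean(per_subj_mae_kcal), mae_kcal_sd = sd(per_subj_mae_kcal),
      mse_pct = mean(per_subj_mse), mse_pct_sd = sd(per_subj_mse),
      mse_kcal = mean(per_subj_mse_kcal),
      max_err_pct = max(abs(err_pct[sel])), max_err_kcal = max(abs(err_kcal[sel])),
      pearson_r = if (sum(sel) >= 3) cor(measured[sel], predicted[sel]) else NA_real_,
      spearman_rho = if (sum(sel) >= 3)
        cor(measured[sel], predicted[sel], method = "spearman") else NA_real_)
  }

  overall <- summarise(rep(TRUE, length(measured)))
  by_group <- lapply(groups, function(g) {
    res <- lapply(unique(g), function(lv) {
      cbind(level = lv, summarise(g == lv))
    })
    do.call(rbind, res)
  })
  structure(list(overall = overall, by_group = by_group,
                 err_pct = err_pct, err_kcal = err_kcal),
            class = "ee_eval")
}

#' @export
print.ee_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<ee_eval> MAE %.1f +- %.1f%% (%.0f +- %.0f kcal/day), MSE %.1f +- %.1f%%\n",
              o$mae_pct, o$mae_pct_sd, o$mae_kcal, o$mae_kcal_sd,
              o$mse_pct, o$mse_pct_sd))
  cat(sprintf("  max |err| %.1f%% (%.0f kcal/day), r = %.3f, rho = %.3f, n = %d windows / %d subjects\n",
              o$max_err_pct, o$max_err_kcal, o$pearson_r, o$spearman_rho,
              o$n_windows, o$n_subjects))
  invisible(x)
}

#' Bland-Altman plot of measured vs predicted EE
#'
#' @param x an `ee_eval` object (needs the stored per-window errors) or
#'   nothing; supply `measured`/`predicted` instead.
#' @param measured,predicted paired values (used when `x` is missing).
#' @param ... passed to [plot()].
#' @return the [bland_altman()] statistics, invisibly.
#' @export
plot.ee_eval <- function(x, measured = NULL, predicted = NULL, ...) {
  d <- x$err_kcal
  m <- if (is.null(measured)) seq_along(d) else (measured + predicted) / 2
  ba <- list(bias = mean(d), sd = sd(d))
  plot(m, d, xlab = "mean of measured and predicted [kcal/day]",
       ylab = "predicted - measured [kcal/day]", ...)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = ba$bias + c(-1.96, 1.96) * ba$sd, lty = 2)
  invisible(ba)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = predicted - measured`; bias is `mean(d)` and the 95%
#' limits of agreement are `bias +- 1.96 * SD(d)` (sample SD, n-1).
#'
#' @param measured,predicted paired measurements, `n >= 3`.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd`.
#' @export
bland_altman <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 3)
  d <- predicted - measured
  s <- sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd = s)
}

#' Paired equivalence test (TOST)
#'
#' Two one-sided paired t-tests of the mean difference against an
#' equivalence zone of `+- zone_frac * mean(measured)`. The pair is declared
#' equivalent when both one-sided tests reject at level `alpha`. With
#' degenerate (zero-variance) differences the mean difference is compared to
#' the zone directly.
#'
#' @param measured,predicted paired samples, `n >= 3`.
#' @param zone_frac half-width of the equivalence zone as a fraction of the
#'   mean measured value (default 0.10).
#' @param alpha significance level of each one-sided test (default 0.05).
#' @return list with `p_lower`, `p_upper`, `equivalent`, `zone`.
#' @export
equivalence_test <- function(measured, predicted, zone_frac = 0.10, alpha = 0.05) {
  stopifnot(length(measured) == length(predicted), length(measured) >= 3)
  d <- predicted - measured
  zone <- zone_frac * mean(measured)
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    eq <- abs(mean(d)) < zone
    return(list(p_lower = as.numeric(!eq), p_upper = as.numeric(!eq),
                equivalent = eq, zone = zone))
  }
  se <- s / sqrt(n)
  # H0: mu <= -zone vs H1: mu > -zone, and H0: mu >= zone vs H1: mu < zone
  p_lower <- pt((mean(d) + zone) / se, df = n - 1, lower.tail = FALSE)
  p_upper <- pt((mean(d) - zone) / se, df = n - 1, lower.tail = TRUE)
  list(p_lower = p_lower, p_upper = p_upper,
       equivalent = p_lower < alpha && p_upper < alpha, zone = zone)
}

#' Pearson and Spearman correlation
#'
#' Thin wrappers with the degenerate-input convention made explicit:
#' constant input yields `NA` with a warning suppressed.
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' @rdname pearson_r
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}
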