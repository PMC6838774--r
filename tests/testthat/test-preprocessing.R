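test_that("Butterworth filters match their analytic frequency response", {
  fs <- 50
  t <- seq(0, 60, 1 / fs)
  mid <- 500:2500  # away from edge transients

  # constant through a high-pass vanishes (once the ~1/cutoff edge
  # transient of the 0.25 Hz filter has decayed)
  hp <- butterworth_filter(rep(3, length(t)), fs, filter_spec("highpass", 2, 0.25))
  expect_lt(max(abs(hp[1200:1800])), 1e-6)

  # 5 Hz sinusoid through the 0.25 Hz high-pass: amplitude preserved within 1%
  x <- sin(2 * pi * 5 * t)
  y <- butterworth_filter(x, fs, filter_spec("highpass", 2, 0.25))
  expect_equal(max(abs(y[mid])) / max(abs(x[mid])), 1, tolerance = 0.01)

  # 0.01 Hz drift through the 0.2 Hz low-pass: passed within 1%
  d <- sin(2 * pi * 0.01 * t)
  z <- butterworth_filter(d, fs, filter_spec("lowpass", 2, 0.2))
  expect_equal(max(abs(z[mid])) / max(abs(d[mid])), 1, tolerance = 0.01)

  # a tone well above a low-pass cutoff is strongly attenuated
  ytone <- butterworth_filter(sin(2 * pi * 10 * t), fs, filter_spec("lowpass", 2, 0.2))
  expect_lt(max(abs(ytone[mid])), 0.01)

  expect_error(butterworth_filter(x, fs, filter_spec("lowpass", 2, 30)),
               class = "iscee_parameter_error")
  expect_error(butterworth_filter(x[1:5], fs, filter_spec("lowpass", 2, 0.2)),
               class = "iscee_parameter_error")
  expect_error(filter_spec("highpass", 0, 0.25), class = "iscee_parameter_error")
})

test_that("zero-phase filtering introduces no lag", {
  fs <- 50
  t <- seq(0, 30, 1 / fs)
  x <- sin(2 * pi * 1 * t)
  y <- butterworth_filter(x, fs, filter_spec("highpass", 2, 0.25))
  cc <- ccf(x, y, lag.max = 25, plot = FALSE)
  expect_identical(as.integer(cc$lag[which.max(cc$acf)]), 0L)
})

test_that("magnitude is the per-sample Euclidean norm", {
  expect_equal(magnitude(matrix(c(3, 4, 0), 1)), 5)
  expect_equal(magnitude(matrix(0, 4, 3)), rep(0, 4))
  set.seed(1)
  m <- matrix(rnorm(300), 100, 3)
  expect_equal(magnitude(m), apply(m, 1, function(r) sqrt(sum(r^2))))
  expect_error(magnitude(matrix(0, 4, 2)), class = "iscee_format_error")
})

test_that("segmentation tiles minutes 4-8 into four non-overlapping windows", {
  recs <- list(fixture_recording("chest", seconds = 480),
               fixture_recording("hip", seconds = 480))
  wins <- segment_activity(recs, c(0, 480), "T01", "act", "sedentary")
  expect_length(wins, 4)
  starts <- vapply(wins, function(w) w$signals$chest$t[1], 0)
  expect_equal(starts, c(240, 300, 360, 420))
  # no sample falls in two windows and the tiling is exact
  all_t <- sort(unlist(lapply(wins, function(w) w$signals$chest$t)))
  expect_identical(anyDuplicated(all_t), 0L)
  expect_equal(length(all_t), 4 * 60 * 50)

  short <- list(fixture_recording("chest", seconds = 300))
  expect_warning(w5 <- segment_activity(short, c(0, 300), "T01", "act", "sedentary"),
                 "1 of 4")
  expect_length(w5, 1)
})

test_that("resting EE is averaged over minutes 14-18 and scaled to kcal/day", {
  fs <- 1
  t <- seq(0, 20 * 60, 1 / fs)
  expect_equal(measured_ree_from_series(rep(1, length(t)), t), 1440)
  # series equal to its minute index: mean of minutes {14..17} worth of samples
  minute <- floor(t / 60)
  got <- measured_ree_from_series(minute, t)
  expect_equal(got, mean(minute[t >= 840 & t < 1080]) * 1440)
  expect_error(measured_ree_from_series(rep(1, 100), t[1:100]),
               class = "iscee_data_error")
})

test_that("gating drops windows with enumerated reasons", {
  good <- fixture_window()
  no_ee <- fixture_window(ee = NA)
  missing <- fixture_window(sites = setdiff(iscee:::SITES, "foot_L"))
  missing$complete <- FALSE
  unsteady <- fixture_window(); unsteady$steady_state <- FALSE
  res <- gate_windows(list(good, no_ee, missing, unsteady))
  expect_length(res$kept, 1)
  expect_setequal(res$dropped$reason, c("missing_ee", "missing_sensor", "non_steady"))
})

test_that("injected dropouts are gated at about their injection rate", {
  cfg <- sim_config(n_subjects = 3, seed = 21, dropout_rate = 0.10)
  cfg$activities <- cfg$activities[c(1, 4, 7, 10), ]
  ds <- simulate_cohort(cfg)
  res <- gate_windows(ds$windows)
  kept_frac <- length(res$kept) / length(ds$windows)
  n <- length(ds$windows)
  expect_lt(abs(kept_frac - 0.9), 3 * sqrt(0.9 * 0.1 / n) + 1e-9)
  expect_true(all(res$dropped$reason == "missing_sensor"))
})

test_that("steady-state flags combine CV and neighbour-step criteria", {
  calm <- rep(2, 60)
  noisy <- 2 + rnorm(60, 0, 1)   # CV ~ 50%
  flags <- steady_state_flags(list(calm, calm + 0.1))
  expect_true(all(flags))
  set.seed(2)
  expect_false(steady_state_flags(list(noisy, calm))[1])
  # large jump to the next window fails the step criterion
  expect_false(all(steady_state_flags(list(calm, calm * 2))))
})
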