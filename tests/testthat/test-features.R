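test_that("statistical features agree with independent definitions", {
  got <- statistical_features(c(1, 2, 3, 4))
  expect_equal(got[["MEAN"]], 2.5)
  expect_equal(got[["MEDIAN"]], 2.5)
  expect_equal(got[["RMS"]], sqrt(7.5))
  cst <- statistical_features(rep(5, 10))
  expect_equal(cst[["SD"]], 0)
  expect_equal(cst[["VAR"]], 0)
  expect_equal(cst[["IQR"]], 0)
  expect_equal(cst[["PERC_99"]], 5)

  set.seed(4)
  for (rep_i in 1:5) {
    x <- rnorm(200 + rep_i)
    got <- statistical_features(x)
    expect_equal(got[["MEAN"]], sum(x) / length(x))
    expect_equal(got[["VAR"]], sum((x - mean(x))^2) / (length(x) - 1))
    expect_equal(got[["SD"]], sqrt(got[["VAR"]]))
    expect_equal(got[["RMS"]], sqrt(sum(x^2) / length(x)))
    for (p in c(1, 3, 5, 25, 75, 95, 99)) {
      expect_equal(got[[paste0("PERC_", p)]], oracle_quantile7(x, p / 100),
                   label = paste0("PERC_", p))
    }
    expect_equal(got[["MEDIAN"]], oracle_quantile7(x, 0.5))
    expect_equal(got[["IQR"]], oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25))
  }
  expect_error(statistical_features(1), class = "iscee_data_error")
})

test_that("activity counts integrate rectified magnitude and scale linearly", {
  fs <- 50
  expect_equal(activity_counts(rep(0, 3000), fs), 0)
  expect_equal(activity_counts(rep(1, 60 * fs), fs), 60)
  set.seed(5)
  x <- rnorm(3000)
  expect_equal(activity_counts(2 * x, fs), 2 * activity_counts(x, fs))
  expect_gte(activity_counts(x, fs), 0)
})

test_that("step detection recovers simulated gait and ignores silence", {
  fs <- 50
  expect_length(detect_steps(rep(0, 3000), fs), 0)
  # single rectangular pulse of 100 deg/s -> one step
  x <- rep(0, 3000); x[1000:1020] <- 100
  expect_length(detect_steps(x, fs), 1)

  # synthetic anti-phase gait at 105 steps/min over 60 s
  cfg <- sim_config(seed = 5, sensor_noise_acc = 0, sensor_noise_gyro = 0,
                    sensor_noise_alt = 0)
  s <- simulate_subject(cfg, 1)
  total <- 0
  for (k in 1:5) {
    w <- simulate_activity_window(s, "walking_4kmh", cfg, seed = 400 + k)
    det <- length(detect_steps(w$signals$ankle_L$gyro[, 3], fs)) +
      length(detect_steps(w$signals$ankle_R$gyro[, 3], fs))
    truth <- length(w$truth$steps_L) + length(w$truth$steps_R)
    expect_equal(det, truth)
    total <- total + det
  }
  expect_lt(abs(total / 5 - 105), 1.5)
})

test_that("step length and distance follow the static method", {
  m <- subject_profile("m", 30, "male", 70, 1.71)
  f <- subject_profile("f", 30, "female", 60, 1.71)
  expect_equal(step_length(m), 0.415 * 1.71)
  expect_equal(step_length(f), 0.413 * 1.71)
  expect_equal(walk_distance(0, 0.71), 0)
  expect_equal(walk_distance(3126, 0.71), 2219.46)
})

test_that("stride-time variance pools same-leg intervals", {
  expect_equal(stride_time_variance(list(seq(0, 10, 1), seq(0.5, 10, 1))), 0)
  expect_equal(stride_time_variance(list(c(0, 1.0, 2.2))), var(c(1.0, 1.2)))
  expect_true(is.na(stride_time_variance(list(c(0, 1)))))
  # independently time-jittered events: interval variance approx 2 * jitter^2
  # (each interval is the difference of two jittered times)
  set.seed(6)
  sims <- replicate(300, {
    tt <- (0:50) * 1 + rnorm(51, 0, 0.05)
    stride_time_variance(list(tt))
  })
  expect_equal(mean(sims), 2 * 0.05^2, tolerance = 0.1)
})

test_that("laterality index is a symmetric bounded ratio", {
  expect_equal(laterality_index(1, 1), 0)
  expect_equal(laterality_index(5, 0), 1)
  expect_equal(laterality_index(0, 5), -1)
  expect_equal(laterality_index(3, 1), 0.5)
  expect_equal(laterality_index(0, 0), 0)
  # antisymmetric under side swap
  expect_equal(laterality_index(2, 7), -laterality_index(7, 2))
})

test_that("cross-correlation feature finds the best lag within +-1 s", {
  fs <- 50
  t <- seq(0, 60, 1 / fs)
  x <- sin(2 * pi * 1 * t)
  expect_equal(cross_correlation_feature(x, x, fs), 1, tolerance = 1e-9)
  # anti-phase sinusoids align at half a period
  y <- sin(2 * pi * 1 * t + pi)
  expect_gt(cross_correlation_feature(x, y, fs), 0.98)
  expect_equal(cross_correlation_feature(x, rep(0, length(t)), fs), 0)
  set.seed(7)
  vals <- replicate(20, cross_correlation_feature(rnorm(3000), rnorm(3000), fs))
  expect_lt(max(vals), 0.2)
  # equals the direct lag-scan definition on short random inputs
  direct <- function(x, y, fs) {
    x <- x - mean(x); y <- y - mean(y); n <- length(x)
    L <- round(fs)
    vals <- vapply(-L:L, function(l) {
      if (l >= 0) sum(x[1:(n - l)] * y[(1 + l):n]) else sum(x[(1 - l):n] * y[1:(n + l)])
    }, 0)
    max(vals) / sqrt(sum(x^2) * sum(y^2))
  }
  for (i in 1:5) {
    a <- rnorm(300); b <- rnorm(300)
    expect_equal(cross_correlation_feature(a, b, 20), direct(a, b, 20))
  }
})

test_that("altitude change is the signed net difference", {
  up <- seq(0, 3, length.out = 100)
  expect_equal(altitude_change(up), 3)
  expect_equal(altitude_change(rev(up)), -3)
  expect_equal(altitude_change(rep(2, 50)), 0)
})

test_that("the feature-name grammar round-trips over the whole bank", {
  bank <- feature_bank()
  expect_length(bank, 351)
  expect_identical(anyDuplicated(bank), 0L)
  stat_names <- bank[grepl("\\(", bank)]
  expect_length(stat_names, 320)  # 6 sites x 36 + 2 ankles x 52
  for (nm in stat_names) {
    p <- parse_feature_name(nm)
    expect_false(is.null(p), label = nm)
    expect_identical(format_feature_name(p$stat, p$signal, p$site_code), nm)
  }
  expect_null(parse_feature_name("MEAN(q_M_DW)"))
  # every preset feature resolves in the bank (plus REE)
  for (preset in c("classifier", "mlr_direct", "ann_direct", "mlr_sedentary",
                   "mlr_low_intensity", "mlr_high_intensity", "mlr_walking",
                   "ann_sedentary", "ann_low_intensity", "ann_high_intensity",
                   "ann_walking")) {
    fs_ <- feature_preset(preset)$features
    expect_true(all(fs_ %in% c(bank, "REE")), label = preset)
  }
  expect_error(feature_preset("nope"), class = "iscee_config_error")
})

test_that("dominant-side codes resolve from handedness", {
  expect_identical(resolve_site("DW", "right"), "wrist_R")
  expect_identical(resolve_site("NDW", "right"), "wrist_L")
  expect_identical(resolve_site("DA", "left"), "ankle_L")
  expect_identical(resolve_site("NDF", "left"), "foot_R")
  expect_identical(resolve_site("Ch", "left"), "chest")
  expect_error(resolve_site("XX"), class = "iscee_config_error")
})

test_that("feature tables carry the full bank and are deterministic", {
  cfg <- sim_config(n_subjects = 1, seed = 31)
  cfg$activities <- cfg$activities[10, ]  # one walking activity
  cfg$windows_per_activity <- 1
  ds <- simulate_cohort(cfg)
  ft <- assemble_feature_table(ds, include_ree = TRUE)
  expect_equal(nrow(ft), 1)
  expect_equal(ncol(ft), length(iscee:::META_COLUMNS) + 351 + 1)
  expect_true("REE" %in% names(ft))
  # restricting the bank to a published set yields exactly those columns
  walkset <- feature_preset("mlr_walking")$features
  ft2 <- assemble_feature_table(ds, bank = walkset, include_ree = TRUE)
  expect_setequal(setdiff(names(ft2), iscee:::META_COLUMNS), walkset)
  expect_error(assemble_feature_table(ds, bank = "NOT_A_FEATURE"),
               class = "iscee_config_error")
  # identical windows (same seed) give identical rows
  ds2 <- simulate_cohort(cfg)
  ft3 <- assemble_feature_table(ds2, include_ree = TRUE)
  expect_identical(ft, ft3)
})
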