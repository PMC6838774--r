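test_that("the speed-profile table is internally consistent", {
  pr <- speed_profiles()
  expect_true(all(pr$ee_per_30min > 0))
  expect_true(all(pr$measured_ee > pr$ree))
  # for the slow speeds the 30-min cost derives from the daily additional EE
  p1 <- iscee:::get_profile(pr, "1")
  expect_equal(p1$ee_per_30min, (3971 - 1477) / 1440 * 30)
  expect_error(iscee:::get_profile(pr, "9"), class = "iscee_config_error")
})

test_that("minute goals reproduce the published translation cells exactly", {
  pr <- speed_profiles()
  m75 <- vapply(c("3", "4", "5", "6"), function(s)
    minutes_for_energy(75, iscee:::get_profile(pr, s)), 0)
  expect_equal(unname(m75), c(27, 16, 18, 14))
  m300 <- vapply(c("3", "4", "5", "6"), function(s)
    minutes_for_energy(300, iscee:::get_profile(pr, s)), 0)
  expect_equal(unname(m300), c(107, 64, 71, 56))
  m300_slow <- vapply(c("1", "2"), function(s)
    minutes_for_energy(300, iscee:::get_profile(pr, s)), 0)
  expect_equal(unname(m300_slow), c(173, 134))
  # identity: a target equal to the 30-min cost takes 30 minutes
  p4 <- iscee:::get_profile(pr, "4")
  expect_equal(minutes_for_energy(p4$ee_per_30min, p4), 30)
})

test_that("step goals follow cadence arithmetic", {
  expect_equal(steps_for_minutes(30, 88), 2640)
  expect_equal(steps_for_minutes(0, 100), 0)
  expect_equal(steps_for_minutes(10, 105), 1050)
})

test_that("additional daily EE is measured minus resting EE", {
  pr <- speed_profiles()
  expect_equal(additional_daily_ee(iscee:::get_profile(pr, "4")), 6752)
  expect_equal(additional_daily_ee(iscee:::get_profile(pr, "1")), 2494)
  same <- data.frame(measured_ee = 2000, ree = 2000)
  expect_equal(additional_daily_ee(same), 0)
  expect_error(additional_daily_ee(data.frame(measured_ee = 1000, ree = 1200)),
               class = "iscee_data_error")
})

test_that("rounding is half away from zero, applied once", {
  expect_equal(round_half_up(56.25), 56)
  expect_equal(round_half_up(17.75), 18)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.5), 3)  # base round() would give 2
})

test_that("the full translation table reproduces the published structure", {
  tab <- build_translation_table()
  pick <- function(g, sp) tab[tab$guideline == g & tab$speed == sp, ]

  # kcal-based minute cells, exact
  expect_equal(vapply(c("3", "4", "5", "6"), function(s)
    pick("75kcal_moderate_pa", s)$goal_minutes, 0),
    c(`3` = 27, `4` = 16, `5` = 18, `6` = 14))
  expect_equal(vapply(c("1", "2", "3", "4", "5", "6"), function(s)
    pick("300kcal_10000_steps", s)$goal_minutes, 0),
    c(`1` = 173, `2` = 134, `3` = 107, `4` = 64, `5` = 71, `6` = 56))
  expect_equal(pick("150kcal_moderate_pa", "average_moderate")$goal_minutes, 38)
  expect_equal(pick("569kcal_1000min_week", "average_moderate")$goal_minutes, 143)
  expect_equal(pick("10000_steps_benchmark", "average_all")$goal_minutes, 110)

  # step-goal cells that depend on unrounded intermediates: within 1%
  published <- list(
    c("30min_moderate_pa", "3", 2648), c("30min_moderate_pa", "4", 3137),
    c("30min_moderate_pa", "5", 3376), c("30min_moderate_pa", "6", 3715),
    c("30min_moderate_pa", "average_moderate", 3126),
    c("75kcal_moderate_pa", "3", 2369), c("75kcal_moderate_pa", "4", 1672),
    c("75kcal_moderate_pa", "5", 1997), c("75kcal_moderate_pa", "6", 1738),
    c("75kcal_moderate_pa", "average_moderate", 1961),
    c("60min_moderate_pa", "average_moderate", 6251),
    c("150kcal_moderate_pa", "average_moderate", 3922),
    c("300kcal_10000_steps", "1", 9724), c("300kcal_10000_steps", "2", 10170),
    c("300kcal_10000_steps", "3", 9477), c("300kcal_10000_steps", "4", 6689),
    c("300kcal_10000_steps", "5", 7989), c("300kcal_10000_steps", "6", 6953),
    c("300kcal_10000_steps", "average_all", 8291),
    c("569kcal_1000min_week", "average_moderate", 14872))
  for (p in published) {
    got <- pick(p[1], p[2])$goal_steps
    want <- as.numeric(p[3])
    expect_lt(abs(got - want) / want, 0.01,
              label = sprintf("%s @ %s: %d vs %s", p[1], p[2], got, p[3]))
  }

  # bout energy of the 30-min rows matches the published per-30-min cost
  expect_equal(vapply(c("3", "4", "5", "6"), function(s)
    pick("30min_moderate_pa", s)$bout_kcal, 0),
    c(`3` = 84, `4` = 141, `5` = 127, `6` = 160))
  # benchmark bout energy within 1% of the published 362 kcal
  expect_lt(abs(pick("10000_steps_benchmark", "average_all")$bout_kcal - 362) / 362,
            0.01)

  # linearity: doubling a kcal basis doubles the unrounded minutes
  pr <- iscee:::get_profile(speed_profiles(), "4")
  expect_equal(300 / pr$ee_per_30min * 30, 2 * (150 / pr$ee_per_30min * 30))
  expect_error(build_translation_table(
    presets = data.frame(guideline = "x", basis = "kcal", value = 10,
                         speeds = "42")),
    class = "iscee_config_error")
})
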