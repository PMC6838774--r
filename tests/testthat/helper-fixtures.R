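# Shared fixtures and independent oracles used across the suite.

fixture_subject <- function(id = "T01", sex = "male", handedness = "right") {
  subject_profile(id = id, age = 45, sex = sex, weight = 80, height = 1.80,
                  handedness = handedness, sport_hours_per_week = 2,
                  scores = c(scim_mobility = 28, six_mwt_m = 500),
                  ree_est = 1700, ree_meas = 1750)
}

# A flat sensor recording with gravity on acc z.
fixture_recording <- function(site = "chest", fs = 50, seconds = 60, t0 = 0) {
  n <- seconds * fs
  t <- t0 + (seq_len(n) - 1) / fs
  sensor_recording(site, t, cbind(rep(0, n), 0, 1), cbind(rep(0, n), 0, 0),
                   rep(1.4, n), fs)
}

fixture_window <- function(subject_id = "T01", class = "sedentary",
                           sites = iscee:::SITES, ee = 1800) {
  activity_window(subject_id, "fixture", class, 0,
                  lapply(sites, fixture_recording), ee_meas = ee)
}

# Tiny two-activity cohort for I/O round trips.
small_cohort <- function(n_subjects = 1, seed = 11) {
  cfg <- sim_config(n_subjects = n_subjects, seed = seed)
  cfg$activities <- cfg$activities[c(1, 10), ]
  cfg$windows_per_activity <- 1
  simulate_cohort(cfg)
}

# Independent type-7 quantile (linear interpolation between order statistics).
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, length(x))
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Brute-force squared-inverse-distance-weighted kNN over raw pairwise
# distances (standardisation applied by the caller).
oracle_knn <- function(train, labels, query, k, classes = iscee:::ACTIVITY_CLASSES) {
  apply(query, 1, function(q) {
    d2 <- rowSums(sweep(train, 2, q)^2)
    ord <- order(d2)[seq_len(k)]
    dk <- d2[ord]; lk <- labels[ord]
    votes <- if (any(dk == 0)) {
      table(factor(lk[dk == 0], levels = classes))
    } else {
      vapply(classes, function(cl) sum(1 / dk[lk == cl]), 0)
    }
    classes[which.max(as.numeric(votes))]
  })
}

expect_exit <- function(expr, code) {
  expect_identical(as.integer(expr), as.integer(code))
}
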