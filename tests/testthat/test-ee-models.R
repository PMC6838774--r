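mk_reg <- function(n, seed = 1, rel_noise = 0) {
  set.seed(seed)
  X <- cbind(a = runif(n, 1, 5), b = runif(n, 0, 3), c = rnorm(n, 2, 0.5))
  mu <- 1500 + 200 * X[, "a"] + 120 * X[, "b"] + 80 * X[, "c"]
  y <- mu * (1 + rnorm(n, 0, rel_noise))
  list(X = X, y = y, beta = c(1500, 200, 120, 80))
}

test_that("relative-error regression interpolates exact linear data", {
  d <- mk_reg(40, seed = 1, rel_noise = 0)
  fit <- relmlr(d$X, d$y)
  expect_equal(unname(coef(fit)), d$beta, tolerance = 1e-8)
  expect_equal(fitted(fit), d$y, tolerance = 1e-8)
  expect_lt(fit$objective, 1e-16)
})

test_that("relative-error regression rejects invalid inputs", {
  d <- mk_reg(20, seed = 2)
  bad_y <- d$y; bad_y[3] <- -1
  expect_error(relmlr(d$X, bad_y), class = "iscee_data_error")
  Xc <- cbind(d$X, dup = d$X[, "a"])  # exact collinearity
  expect_error(relmlr(Xc, d$y), "dup", class = "iscee_data_error")
  expect_error(relmlr(d$X[1:3, ], d$y[1:3]), class = "iscee_data_error")
})

test_that("intercept-only fit on equal responses returns that response", {
  y <- rep(1234, 10)
  X <- matrix(numeric(0), 10, 0)
  fit <- relmlr(X, y, features = character())
  expect_equal(unname(coef(fit)), 1234)
  expect_equal(predict(fit, matrix(numeric(0), 3, 0)), rep(1234, 3))
})

test_that("the closed form equals OLS when all responses are equal", {
  set.seed(3)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  y <- rep(2000, 30) # equal weights: WLS == OLS
  y_j <- y + X[, "a"] * 0   # keep y constant
  fit <- relmlr(X, y_j)
  ols <- lm(y_j ~ X)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("the relative-error objective beats OLS at its own criterion", {
  for (seed in 1:5) {
    d <- mk_reg(60, seed = seed, rel_noise = 0.2)
    fit <- relmlr(d$X, d$y)
    ols <- lm.fit(cbind(1, d$X), d$y)$coefficients
    obj <- function(b) sum(((cbind(1, d$X) %*% b - d$y) / d$y)^2)
    expect_lte(fit$objective, obj(ols) + 1e-12)
  }
})

test_that("closed-form solution matches a numerical minimizer", {
  for (seed in 1:10) {
    n <- 30
    d <- mk_reg(n, seed = seed, rel_noise = 0.15)
    fit <- relmlr(d$X, d$y)
    obj <- function(b) sum(((cbind(1, d$X) %*% b - d$y) / d$y)^2)
    num <- optim(coef(fit) * runif(4, 0.5, 1.5), obj, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-15))
    expect_lt(abs(fit$objective - num$value) / max(num$value, 1e-12), 1e-6)
    expect_lte(fit$objective, num$value + 1e-12)
  }
})

test_that("prediction is an affine evaluation with strict feature checks", {
  d <- mk_reg(25, seed = 4)
  fit <- relmlr(d$X, d$y)
  row <- matrix(c(2, 1, 3), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(predict(fit, row),
               sum(coef(fit) * c(1, 2, 1, 3)))
  expect_error(predict(fit, matrix(1, 1, 2, dimnames = list(NULL, c("a", "b")))))
  # training rows of a perfect-fit model reproduce training y
  d0 <- mk_reg(25, seed = 5, rel_noise = 0)
  f0 <- relmlr(d0$X, d0$y)
  expect_equal(predict(f0, d0$X), d0$y, tolerance = 1e-8)
})

test_that("multiplicative-noise coefficients are recovered within 2%", {
  # wide-dynamic-range activity feature: identification strong enough that
  # the 5% relative noise leaves under 2% coefficient error at n = 500
  set.seed(42)
  n <- 500
  X <- cbind(ac = exp(runif(n, 0, 4)))
  beta <- c(1000, 100)
  y <- as.numeric(cbind(1, X) %*% beta) * (1 + rnorm(n, 0, 0.05))
  fit <- relmlr(X, y)
  expect_lt(max(abs(coef(fit) - beta) / abs(beta)), 0.02)
})

test_that("the network ensemble learns a linear map and is reproducible", {
  set.seed(10)
  n <- 250
  X <- cbind(a = runif(n, -1, 2), b = runif(n, 0, 3))
  y <- 1800 + 300 * X[, "a"] + 150 * X[, "b"]
  idx <- 1:200
  fit <- ann_ensemble(X[idx, ], y[idx], hidden_units = 3, ensemble_size = 5,
                      seed = 7)
  pred <- predict(fit, X[-idx, ])
  ss_res <- sum((pred - y[-idx])^2)
  ss_tot <- sum((y[-idx] - mean(y[-idx]))^2)
  expect_gt(1 - ss_res / ss_tot, 0.99)
  fit2 <- ann_ensemble(X[idx, ], y[idx], hidden_units = 3, ensemble_size = 5,
                       seed = 7)
  expect_identical(predict(fit2, X[-idx, ]), pred)
})

test_that("averaging networks reduces held-out risk in most seeds", {
  # large held-out set so the risk estimate itself is not the bottleneck
  set.seed(20)
  n_tr <- 120; n_te <- 2000
  X <- cbind(a = runif(n_tr + n_te, -2, 2))
  y <- 2000 + 400 * sin(X[, "a"]) + rnorm(n_tr + n_te, 0, 60)
  tr <- seq_len(n_tr)
  wins <- 0
  for (s in 1:10) {
    e1 <- ann_ensemble(X[tr, , drop = FALSE], y[tr], hidden_units = 3,
                       ensemble_size = 1, seed = 100 + s)
    e15 <- ann_ensemble(X[tr, , drop = FALSE], y[tr], hidden_units = 3,
                        ensemble_size = 15, seed = 100 + s)
    err1 <- mean((predict(e1, X[-tr, , drop = FALSE]) - y[-tr])^2)
    err15 <- mean((predict(e15, X[-tr, , drop = FALSE]) - y[-tr])^2)
    if (err15 <= err1) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

toy_table <- function() {
  # two activity classes with different linear EE laws on feature u
  set.seed(30)
  rows <- do.call(rbind, lapply(1:4, function(subj) {
    u <- runif(20, 1, 4)
    cls <- rep(iscee:::ACTIVITY_CLASSES, each = 5)
    mu <- ifelse(cls == "sedentary", 1500 + 100 * u,
          ifelse(cls == "low_intensity", 1800 + 250 * u,
          ifelse(cls == "high_intensity", 2200 + 500 * u, 2000 + 400 * u)))
    data.frame(subject_id = paste0("S", subj), activity_name = "toy",
               activity_class = cls, window_index = 0, ee_meas = mu,
               u = u, check.names = FALSE)
  }))
  rows
}

test_that("bundles fit per-class models with the published feature keys", {
  ft <- toy_table()
  sets <- list(sedentary = "u", low_intensity = "u", high_intensity = "u",
               walking = "u")
  bundle <- fit_ee_bundle(ft, "class_conditional", "mlr", feature_sets = sets)
  expect_named(bundle$models, iscee:::ACTIVITY_CLASSES)
  # true-label routing on perfectly fit per-class toys reproduces y
  pred <- predict(bundle, ft, class_source = "true_label")
  expect_equal(as.numeric(pred), ft$ee_meas, tolerance = 1e-8)
  # a deliberately mislabelled window is scored by the wrong class model
  wrong <- ft[1, ]
  wrong$activity_class <- "high_intensity"  # truly sedentary
  p_wrong <- predict(bundle, wrong, class_source = "true_label")
  expect_equal(as.numeric(p_wrong),
               as.numeric(predict(bundle$models$high_intensity, wrong)))
  expect_false(isTRUE(all.equal(as.numeric(p_wrong), wrong$ee_meas)))
  # too few windows in a class is an error
  expect_error(fit_ee_bundle(ft[ft$activity_class != "walking" | ft$u < 0, ],
                             "class_conditional", "mlr", feature_sets = sets),
               class = "iscee_data_error")

  # the default presets carry the published feature keys
  expect_setequal(feature_preset("mlr_walking")$features,
                  c("REE", "weight", "MEDIAN(a_M_Ch)", "PERC_1(w_M_Hi)",
                    "IQR(a_M_NDF)", "MEDIAN(w_M_NDF)"))
  expect_setequal(feature_preset("mlr_direct")$features,
                  c("REE", "MEAN(a_M_DW)", "PERC_1(a_M_Ch)", "MEAN(w_M_DW)",
                    "VAR(H_Ch)", "PERC_25(a_M_DA)", "VAR(a_M_NDF)"))
})

test_that("classifier-routed prediction uses the stored gate", {
  ft <- toy_table()
  sets <- list(sedentary = "u", low_intensity = "u", high_intensity = "u",
               walking = "u")
  bundle <- fit_ee_bundle(ft, "class_conditional", "mlr", feature_sets = sets)
  expect_error(predict(bundle, ft, class_source = "classifier"),
               class = "iscee_config_error")
  gate <- knn_gate(ft, ft$activity_class, k = 3, features = "u")
  bundle$classifier <- gate
  pred <- predict(bundle, ft, class_source = "classifier")
  expect_identical(attr(pred, "routed_class"),
                   as.character(predict(gate, ft)))
})

test_that("model JSON serialisation round-trips predictions", {
  ft <- toy_table()
  fit <- relmlr(ft, ft$ee_meas, features = "u")
  p1 <- file.path(tempdir(), "m1.json")
  write_model(fit, p1)
  expect_equal(predict(read_model(p1), ft), predict(fit, ft))

  gate <- knn_gate(ft, ft$activity_class, k = 3, features = "u")
  p2 <- file.path(tempdir(), "m2.json")
  write_model(gate, p2)
  expect_identical(as.character(predict(read_model(p2), ft)),
                   as.character(predict(gate, ft)))

  sets <- list(sedentary = "u", low_intensity = "u", high_intensity = "u",
               walking = "u")
  bundle <- fit_ee_bundle(ft, "class_conditional", "mlr", feature_sets = sets,
                          classifier = gate)
  p3 <- file.path(tempdir(), "m3.json")
  write_model(bundle, p3)
  expect_equal(as.numeric(predict(read_model(p3), ft, class_source = "classifier")),
               as.numeric(predict(bundle, ft, class_source = "classifier")))
})
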