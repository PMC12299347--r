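test_that("prediction is the affine combination of the covariates", {
  m <- cl_residual_model()
  expect_equal(as.numeric(predict(m, 0, 0, 0)), 38.518)
  expect_equal(as.numeric(predict(m, 270, 112.5, 12.9)),
               38.518 - 0.219 * 270 + 0.143 * 112.5 + 0.557 * 12.9)
  expect_equal(as.numeric(predict(m, 270, 112.5, 12.9)), 2.6608,
               tolerance = 1e-10)
  expect_equal(as.numeric(predict(m, 100, 37.5, 9.8)), 27.4391,
               tolerance = 1e-10)

  # affine in the inputs before clamping
  set.seed(3)
  for (i in 1:20) {
    x <- runif(3, 0, c(300, 112, 13)); y <- runif(3, 0, c(300, 112, 13))
    a <- runif(1)
    z <- a * x + (1 - a) * y
    expect_equal(as.numeric(predict(m, z[1], z[2], z[3], clamp = FALSE)),
                 a * as.numeric(predict(m, x[1], x[2], x[3], clamp = FALSE)) +
                   (1 - a) * as.numeric(predict(m, y[1], y[2], y[3], clamp = FALSE)),
                 tolerance = 1e-10)
  }

  # monotone: decreasing in rainfall, increasing in dose and clay
  r <- seq(0, 300, 25)
  expect_true(all(diff(predict(m, r, 75, 12, clamp = FALSE)) < 0))
  d <- seq(0, 112.5, 12.5)
  expect_true(all(diff(predict(m, 100, d, 12, clamp = FALSE)) > 0))
  cl <- seq(0, 30, 3)
  expect_true(all(diff(predict(m, 100, 75, cl, clamp = FALSE)) > 0))
})

test_that("negative predictions clamp to zero and extrapolation is flagged", {
  m <- cl_residual_model()
  p <- predict(m, 300, 0, 9.8)
  expect_equal(as.numeric(p), 0)
  expect_true("clamped" %in% flags(p))
  expect_lt(as.numeric(predict(m, 300, 0, 9.8, clamp = FALSE)), 0)
  expect_true("extrapolation" %in% flags(predict(m, 100, 75, 30)))
  expect_null(flags(predict(m, 100, 75, 12)))
  expect_error(predict(m, NA, 0, 0), "finite")
  expect_error(predict(m, 10, 10, 150), "\\[0, 100\\]")
})

test_that("required rainfall inverts the model for its rainfall covariate", {
  m <- cl_residual_model()
  expect_equal(as.numeric(required_rainfall(m, 20, 75, 12.9)),
               (38.518 + 0.143 * 75 + 0.557 * 12.9 - 20) / 0.219)
  expect_equal(as.numeric(required_rainfall(m, 20, 75, 12.9)), 166.34,
               tolerance = 1e-4)
  # intercept already at target
  expect_equal(as.numeric(required_rainfall(m, 38.518, 0, 0)), 0)
  # target above any prediction: flagged zero
  rr <- required_rainfall(m, 60, 0, 0)
  expect_equal(as.numeric(rr), 0)
  expect_identical(flags(rr), "already_below_target")
  degen <- cl_residual_model(slope_rain = 0)
  expect_error(required_rainfall(degen, 20, 75, 12.9), "degenerate")
})

test_that("allowable dose inverts the model for its dose covariate", {
  m <- cl_residual_model()
  zero_dose <- as.numeric(predict(m, 100, 0, 12.9))
  expect_equal(zero_dose, 23.8033, tolerance = 1e-10)
  expect_equal(as.numeric(allowable_cl_dose(m, 30, 100, 12.9)),
               (30 - zero_dose) / 0.143, tolerance = 1e-10)
  # target below the zero-dose prediction is unreachable
  d <- allowable_cl_dose(m, 20, 100, 12.9)
  expect_equal(as.numeric(d), 0)
  expect_identical(flags(d), "target_unreachable_at_zero_dose")
  degen <- cl_residual_model(slope_cl = 0)
  expect_error(allowable_cl_dose(degen, 20, 100, 12.9), "degenerate")
})

test_that("both inversions compose with predict to the identity", {
  m <- cl_residual_model()
  grid <- expand.grid(rain = seq(0, 250, 50), dose = c(0, 37.5, 75, 112.5),
                      clay = c(9.8, 12.9))
  for (i in seq_len(nrow(grid))) {
    y <- as.numeric(predict(m, grid$rain[i], grid$dose[i], grid$clay[i],
                            clamp = FALSE))
    if (y < 0) next
    expect_equal(as.numeric(required_rainfall(m, y, grid$dose[i], grid$clay[i])),
                 grid$rain[i], tolerance = 1e-9)
    expect_equal(as.numeric(allowable_cl_dose(m, y, grid$rain[i], grid$clay[i])),
                 grid$dose[i], tolerance = 1e-9)
  }
})

test_that("refitting a noiseless grid recovers the coefficients exactly", {
  m <- cl_residual_model()
  g <- expand.grid(rainfall = seq(0, 300, 50),
                   cl_rate = c(0, 37.5, 75, 112.5),
                   clay = c(9.8, 12.9))
  g$measured <- as.numeric(predict(m, g$rainfall, g$cl_rate, g$clay,
                                   clamp = FALSE))
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_residual_model(g))
  expect_equal(unname(coef(fit)),
               c(38.518, -0.219, 0.143, 0.557), tolerance = 1e-9)
})

test_that("refit matches the normal-equations oracle and reports SEs", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    g <- data.frame(rainfall = runif(n, 0, 300),
                    cl_rate = runif(n, 0, 112.5),
                    clay = runif(n, 8, 14))
    g$measured <- oracle_predict(g$rainfall, g$cl_rate, g$clay) + rnorm(n, 0, 2)
    fit <- fit_residual_model(g)
    expect_equal(unname(coef(fit)),
                 oracle_ols(cbind(1, g$rainfall, g$cl_rate, g$clay), g$measured),
                 tolerance = 1e-8)
    expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  }
})

test_that("noisy refit lands within 3 standard errors of the truth", {
  set.seed(56)
  g <- expand.grid(rainfall = seq(0, 300, 50),
                   cl_rate = c(0, 37.5, 75, 112.5),
                   clay = c(9.8, 12.9))   # n = 56
  g$measured <- oracle_predict(g$rainfall, g$cl_rate, g$clay) + rnorm(56, 0, 1)
  fit <- fit_residual_model(g)
  dev <- abs(coef(fit) - default_coefs) / fit$se
  expect_true(all(dev < 3))
})

test_that("rank-deficient designs raise a singular-design error naming columns", {
  g <- data.frame(rainfall = seq(0, 100, 20), cl_rate = 37.5, clay = 12.9)
  g$measured <- oracle_predict(g$rainfall, g$cl_rate, g$clay)
  expect_error(fit_residual_model(g), "singular design")
  expect_error(fit_residual_model(g), "slope_clay")
  expect_error(fit_residual_model(g[1:3, ]), "at least 5")
})
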