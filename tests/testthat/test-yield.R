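test_that("relative yield is the treated/control percentage", {
  expect_equal(relative_yield(28, 28), 100)
  expect_equal(relative_yield(26.6, 28), 95)
  expect_equal(relative_yield(14, 28), 50)
  expect_error(relative_yield(10, 0), "positive")
})

test_that("dose-response fitting recovers a known quadratic and its optimum", {
  d <- c(0, 25, 50, 75, 100, 125)
  ry <- 100 + 0.05 * d - 0.001 * d^2
  f <- fit_dose_response(d, ry)
  expect_equal(f$p0, 100, tolerance = 1e-8)
  expect_equal(f$p1, 0.05, tolerance = 1e-8)
  expect_equal(f$p2, -0.001, tolerance = 1e-8)
  expect_equal(f$optimum_dose, 25, tolerance = 1e-8)

  # flat response has no descending limb
  expect_warning(flat <- fit_dose_response(c(0, 30, 60, 90), rep(100, 4)),
                 "no descending limb")
  expect_identical(flags(flat), "no_descending_limb")
  expect_true(is.na(flat$optimum_dose))
  expect_error(fit_dose_response(c(10, 20, 30, 40), c(1, 2, 3, 4)),
               "zero-dose")
})

test_that("dose-response fits match the normal-equations oracle", {
  set.seed(44)
  for (rep in 1:6) {
    n <- sample(c(8, 20, 50), 1)
    d <- c(0, runif(n - 1, 0, 120))
    ry <- 100 + 0.16 * d - 0.003 * d^2 + rnorm(n, 0, 1)
    f <- fit_dose_response(d, ry)
    o <- oracle_quadfit(d, ry)
    expect_equal(f$p0, o$c, tolerance = 1e-8)
    expect_equal(f$p1, o$b, tolerance = 1e-8)
    expect_equal(f$p2, o$a, tolerance = 1e-8)
  }
})

test_that("noisy dose-response recovery is median-unbiased for the optimum", {
  # the vertex of a flat quadratic is weakly identified at sigma = 1, n = 12;
  # the Monte-Carlo median over replicates recovers it closely
  truth_opt <- 25
  set.seed(17)
  opts <- vapply(1:20, function(i) {
    d <- rep(c(0, 20, 40, 60), each = 3)
    ry <- 100 + 0.05 * d - 0.001 * d^2 + rnorm(12, 0, 1)
    suppressWarnings(fit_dose_response(d, ry)$optimum_dose)
  }, numeric(1))
  # occasional convex fits yield no optimum and drop out of the median
  expect_lt(abs(median(opts, na.rm = TRUE) - truth_opt) / truth_opt, 0.15)
})

test_that("safe dose range solves the descending limb and converts to KCl", {
  d <- c(0, 25, 50, 75, 100, 125)
  f <- fit_dose_response(d, 100 + 0.05 * d - 0.001 * d^2)
  sr <- safe_dose_range(f)
  expect_equal(sr$dose_ry100, 50, tolerance = 1e-8)
  expect_equal(sr$dose_ry95, 100, tolerance = 1e-8)
  expect_equal(sr$kcl_ry100, 50 / 0.45, tolerance = 1e-8)
  # cross-check against a brute-force root scan
  expect_equal(sr$dose_ry100, oracle_descending_root(100, 0.05, -0.001, 100),
               tolerance = 1e-2)
  expect_equal(sr$dose_ry95, oracle_descending_root(100, 0.05, -0.001, 95),
               tolerance = 1e-2)
  # plug-back: RY at the solved doses equals the target
  expect_equal(predict(f, sr$dose_ry100), 100, tolerance = 1e-9)
  expect_equal(predict(f, sr$dose_ry95), 95, tolerance = 1e-9)
  expect_lt(sr$dose_ry100, sr$dose_ry95)

  expect_warning(flat <- fit_dose_response(c(0, 30, 60, 90), rep(100, 4)))
  expect_error(safe_dose_range(flat), "descending")
})

test_that("reported dose bounds convert to the published KCl equivalents", {
  # loam bounds 51.6 and 73.8 kg Cl/ha at a 45 % Cl grade
  expect_equal(round(51.6 / 0.45), 115)
  expect_equal(round(73.8 / 0.45), 164)
  # the conversion the safe_range object applies is the same /0.45
  curve <- default_yield_curve("loam")
  d <- c(0, 20, 40, 60, 80)
  f <- fit_dose_response(d, curve$p0 + curve$p1 * d + curve$p2 * d^2)
  sr <- safe_dose_range(f)
  expect_equal(sr$dose_ry100, 51.6, tolerance = 1e-6)
  expect_equal(sr$dose_ry95, 73.8, tolerance = 1e-6)
  expect_equal(round(sr$kcl_ry100), 115)
  expect_equal(round(sr$kcl_ry95), 164)
  # KCl conversion round-trips exactly
  expect_equal(sr$kcl_ry95 * 0.45, sr$dose_ry95, tolerance = 1e-12)
})

test_that("a curve that never reaches 100 returns only the flagged 95 bound", {
  d <- c(0, 20, 40, 60, 80)
  ry <- 98 - 0.02 * d - 0.0005 * d^2   # concave, always below 100
  f <- suppressWarnings(fit_dose_response(d, ry))
  sr <- safe_dose_range(f)
  expect_true(is.na(sr$dose_ry100))
  expect_identical(flags(sr), "ry100_unreachable")
  expect_true(is.finite(sr$dose_ry95))
  expect_equal(predict(f, sr$dose_ry95), 95, tolerance = 1e-9)
})

test_that("toxicity classes follow the rubric with flagged gap-filling", {
  expect_identical(as.character(classify_toxicity(97)), "safe")
  expect_identical(as.character(classify_toxicity(85)), "mild")
  expect_identical(as.character(classify_toxicity(45)), "severe")
  expect_identical(as.character(classify_toxicity(101)), "no_suppression")
  cls <- classify_toxicity(c(92, 60))
  expect_identical(as.character(cls), c("marginal", "moderate"))
  expect_identical(flags(cls), "gap_filled")
  expect_null(flags(classify_toxicity(c(97, 85))))
  expect_error(classify_toxicity(-5), "non-negative")
})
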