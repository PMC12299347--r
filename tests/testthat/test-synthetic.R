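test_that("rainfall series hit the season total and are reproducible", {
  cfg <- generator_config(seed = 5)
  r1 <- generate_rainfall(cfg)
  r2 <- generate_rainfall(cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$rain_mm >= 0))
  expect_equal(sum(r1$rain_mm), 340, tolerance = 1e-9)
  expect_equal(nrow(r1), 130)

  # a wetter season at the same seed is a pointwise rescaling:
  # same wet days, same event count, scaled amounts
  r700 <- generate_rainfall(generator_config(seed = 5, season_rain_total = 700))
  expect_identical(r700$rain_mm > 0, r1$rain_mm > 0)
  wet <- r1$rain_mm > 0
  expect_equal(r700$rain_mm[wet] / r1$rain_mm[wet],
               rep(700 / 340, sum(wet)), tolerance = 1e-9)
})

test_that("profile tables are deterministic and structurally valid", {
  cfg <- generator_config(seed = 9)
  o1 <- generate_profile_timeseries(cfg)
  o2 <- generate_profile_timeseries(cfg)
  attr(o1, "truth") <- attr(o2, "truth") <- NULL
  expect_identical(o1, o2)
  expect_true(all(o1$cl_mgkg >= 0))
  expect_setequal(unique(o1$treatment), c("CK", "L", "M", "H"))
  expect_setequal(unique(o1$layer_top_cm), c(0, 15, 30))
  expect_silent(validate_observations(o1))
  # sampling days increase with the rainfall milestones
  sched <- attr(generate_profile_timeseries(cfg), "truth")$schedule
  expect_true(all(diff(sched$das) >= 0))
  expect_true(all(diff(sched$cum_rain) > 0))
})

test_that("a noiseless trial reproduces the generating truth end to end", {
  cfg <- generator_config(seed = 2, noise_sd = 0)
  tr <- simulate_trial(cfg)
  obs <- tr$observations

  # CK carries the rain-declining background only
  ck <- obs[obs$treatment == "CK", ]
  expect_equal(ck$cl_mgkg, tr$truth$background(ck$cum_rain_mm),
               tolerance = 1e-9)
  expect_true(all(diff(tr$truth$background(c(0, 100, 200, 300))) < 0))

  # budgets recover the true leaching efficiency exactly
  b <- compute_budgets(obs, cfg$bulk_density, plant_uptake = cfg$plant_uptake)
  for (i in seq_len(nrow(b))) {
    expect_equal(b$leaching_factor[i],
                 tr$truth$efficiency(b$cum_rain[i], b$cl_applied[i]),
                 tolerance = 1e-6)
  }

  # layer stocks match the truth at every milestone
  h <- obs[obs$treatment == "H" & obs$replicate == 1, ]
  for (rain in unique(h$cum_rain_mm)) {
    sub <- h[h$cum_rain_mm == rain, ]
    sub <- sub[order(sub$layer_top_cm), ]
    exo <- cl_stock(sub$cl_mgkg - tr$truth$background(rain),
                    cfg$bulk_density, 15)
    expect_equal(exo, unname(tr$truth$layer_stocks(rain, 112.5)),
                 tolerance = 1e-6)
  }
})

test_that("noiseless yields recover the safe range of the generating curve", {
  cfg <- generator_config(seed = 3, yield_cv = 0,
                          cl_doses = c(0, 25, 50, 75, 100))
  y <- generate_yield(cfg, curve = list(p0 = 100, p1 = 0.05, p2 = -0.001))
  expect_equal(y$yield_t_ha[y$dose == 0], rep(cfg$ck_yield, 3), tolerance = 1e-9)
  agg <- aggregate(yield_t_ha ~ dose, data = y, FUN = mean)
  ry <- relative_yield(agg$yield_t_ha, mean(y$yield_t_ha[y$dose == 0]))
  sr <- safe_dose_range(fit_dose_response(agg$dose, ry))
  expect_equal(sr$dose_ry100, 50, tolerance = 1e-6)
  expect_equal(sr$dose_ry95, 100, tolerance = 1e-6)
})

test_that("noisy yields keep the fitted optimum near the truth on average", {
  curve <- default_yield_curve("loam")
  truth_opt <- -curve$p1 / (2 * curve$p2)
  opts <- vapply(1:20, function(s) {
    cfg <- generator_config(seed = s, yield_cv = 0.05)
    y <- generate_yield(cfg, curve = curve)
    agg <- aggregate(yield_t_ha ~ dose, data = y, FUN = mean)
    ry <- relative_yield(agg$yield_t_ha, mean(y$yield_t_ha[y$dose == 0]))
    fit_dose_response(agg$dose, ry)$optimum_dose
  }, numeric(1))
  expect_lt(abs(median(opts) - truth_opt) / truth_opt, 0.20)
})

test_that("sandy loam leaches faster than loam at low rain and converges later on", {
  cfgL <- generator_config(seed = 1, texture = "loam")
  cfgS <- generator_config(seed = 1, texture = "sandy_loam")
  for (rain in c(20, 53, 91, 150)) {
    expect_gt(clleach:::true_efficiency(cfgS, rain),
              clleach:::true_efficiency(cfgL, rain))
  }
  # texture effect fades at high rainfall
  dL <- clleach:::true_efficiency(cfgL, 300)
  dS <- clleach:::true_efficiency(cfgS, 300)
  expect_lt(abs(dL - dS), 0.05)
  # pulse centre advances faster in sandy loam
  wL <- clleach:::true_layer_weights(cfgL, 100)
  wS <- clleach:::true_layer_weights(cfgS, 100)
  expect_gt(wS[3], wL[3])
  expect_equal(sum(wL), 1, tolerance = 1e-12)
})
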