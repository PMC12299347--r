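# Independent brute-force oracles: plain loops and normal equations,
# deliberately sharing no code with the package internals.

oracle_metrics <- function(me, mo) {
  n <- length(me)
  sme <- 0; for (v in me) sme <- sme + v
  mbar <- sme / n
  sse <- 0; sst <- 0; sdev <- 0; ssum <- 0
  for (i in seq_len(n)) {
    sse <- sse + (me[i] - mo[i])^2
    sst <- sst + (mbar - me[i])^2
    sdev <- sdev + (me[i] - mo[i])
    ssum <- ssum + me[i]
  }
  mobar <- 0; for (v in mo) mobar <- mobar + v; mobar <- mobar / n
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_len(n)) {
    num <- num + (me[i] - mbar) * (mo[i] - mobar)
    d1 <- d1 + (me[i] - mbar)^2
    d2 <- d2 + (mo[i] - mobar)^2
  }
  rmse <- sqrt(sse / n)
  list(r = num / sqrt(d1 * d2),
       r2 = 1 - sse / sst,
       rmse = rmse,
       nrmse = rmse / (max(me) - min(me)),
       pbias = sdev / ssum * 100)
}

# normal-equations least squares: X is the design matrix including intercept
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

oracle_quadfit <- function(x, y) {
  cf <- oracle_ols(cbind(1, x, x^2), y)
  list(c = cf[1], b = cf[2], a = cf[3])
}

# grid-scan root finder for RY(d) = target on the descending limb
oracle_descending_root <- function(p0, p1, p2, target, upper = 1000) {
  opt <- -p1 / (2 * p2)
  d <- seq(opt, upper, length.out = 2e5)
  ry <- p0 + p1 * d + p2 * d^2
  d[which.min(abs(ry - target))]
}

default_coefs <- c(intercept = 38.518, slope_rain = -0.219,
                   slope_cl = 0.143, slope_clay = 0.557)

# raw affine prediction, independent of the package's predict method
oracle_predict <- function(rain, dose, clay, cf = default_coefs) {
  cf[["intercept"]] + cf[["slope_rain"]] * rain +
    cf[["slope_cl"]] * dose + cf[["slope_clay"]] * clay
}

make_obs_df <- function(n = 3) {
  data.frame(site_id = "s1", texture = "loam", treatment = "L",
             das = seq_len(n), cum_rain_mm = seq_len(n) * 10,
             layer_top_cm = 0, layer_bottom_cm = 15,
             cl_mgkg = 10 + seq_len(n), so4_mgkg = 70, replicate = 1)
}
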