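## Synthetic field-trial generator. Emulates rain-fed chloride leaching
## trials: a daily rainfall series, layer-wise Cl- (and inert SO4) profile
## observations over the season, and tuber yields, with the generating truth
## retained for recovery tests.
##
## Mechanism: the applied dose enters the 0-15 cm layer and migrates downward
## as a Gaussian pulse over depth whose centre and spread grow with cumulative
## rainfall (faster in sandy loam than loam). The fraction leached below
## 45 cm follows a monotone efficiency curve anchored at field-reported
## milestones (30 % efficiency near 91 mm rain in loam / 53 mm in sandy loam;
## ~85 % leached by 270 mm; end-of-season residual under 10 %). Mass is
## conserved: residual profile stock + leached fraction = applied dose.

restore_rng <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

texture_defaults <- function(texture) {
  switch(texture,
    loam = list(
      bulk_density = 1.32, clay = 12.9,
      eff_rain = c(0, 20, 91, 200, 244, 300),
      eff_frac = c(0, 0.05, 0.30, 0.65, 0.80, 0.90),
      pulse_velocity = 0.09,     # cm of pulse-centre advance per mm rain
      ry_bounds = c(ry100 = 51.6, ry95 = 73.8)),
    sandy_loam = list(
      bulk_density = 1.36, clay = 9.8,
      eff_rain = c(0, 20, 53, 150, 230, 300),
      eff_frac = c(0, 0.09, 0.30, 0.60, 0.80, 0.915),
      pulse_velocity = 0.12,
      ry_bounds = c(ry100 = 96.3, ry95 = 106.8)),
    stop("unknown texture: ", texture, call. = FALSE))
}

#' Configuration for the synthetic trial generator
#'
#' Bundles every tunable of the generator. Defaults reproduce the study
#' conditions: growing-season rainfall presets of 340 or 700 mm over about
#' 130 days, doses 0/37.5/75/112.5 kg Cl/ha in triplicate, background
#' water-soluble Cl- in the 8.6-12.5 mg/kg range, Gaussian measurement noise
#' of 1 mg/kg, and texture-specific leaching calibration (sandy loam leaches
#' faster than loam at low rain, converging by 270 mm).
#'
#' @param seed integer RNG seed; every generated table is reproducible from it.
#' @param season_rain_total total growing-season rainfall, mm (presets 340, 700).
#' @param season_days length of the season, days.
#' @param texture `"loam"` or `"sandy_loam"`.
#' @param background_cl background water-soluble Cl-, mg/kg (8.6-12.5).
#' @param cl_doses chloride doses, kg/ha; the zero dose is the control (CK).
#' @param noise_sd Gaussian measurement noise on concentrations, mg/kg.
#' @param n_replicates field replicates per treatment.
#' @param sampling_rain cumulative-rainfall milestones (mm) at which profiles
#'   are sampled; sampling days are derived from the rainfall series as the
#'   day each milestone is first crossed. Milestones beyond the season total
#'   are dropped.
#' @param plant_uptake assumed plant Cl absorption fraction for budgets.
#' @param background_decay length scale (mm of cumulative rain) of the
#'   within-season exponential decline of the background Cl- itself;
#'   background is as mobile as the applied dose, so control profiles also
#'   lose chloride as the season wets up.
#' @param bulk_density,clay soil properties; default by texture.
#' @param pulse_velocity pulse-centre advance, cm per mm of rain; default by
#'   texture (sandy loam faster).
#' @param pulse_spread intercept and slope of the pulse spread in cm:
#'   `sd(rain) = pulse_spread[1] + pulse_spread[2] * rain`.
#' @param eff_rain,eff_frac calibration anchors of the leaching-efficiency
#'   curve (monotone spline through them); default by texture.
#' @param dose_sensitivity relative change of efficiency per kg/ha of dose
#'   about the middle dose (higher doses leach slightly more efficiently).
#' @param ck_yield control tuber yield, t/ha.
#' @param yield_cv coefficient of variation of replicate yields.
#' @param so4_background background SO4^2- content, mg/kg (inert covariate).
#' @param early_heavy_prob probability that an early-season wet day is a
#'   heavy event (convective storms early in the season).
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(seed = 1L,
                             season_rain_total = 340,
                             season_days = 130,
                             texture = c("loam", "sandy_loam"),
                             background_cl = 10.5,
                             cl_doses = c(0, 37.5, 75, 112.5),
                             noise_sd = 1.0,
                             n_replicates = 3L,
                             sampling_rain = c(20, 70, 110, 150, 200, 240, 270, 300),
                             plant_uptake = 0.05,
                             background_decay = 130,
                             bulk_density = NULL,
                             clay = NULL,
                             pulse_velocity = NULL,
                             pulse_spread = c(4.2, 0.055),
                             eff_rain = NULL,
                             eff_frac = NULL,
                             dose_sensitivity = 8e-4,
                             ck_yield = 28,
                             yield_cv = 0.05,
                             so4_background = 78,
                             early_heavy_prob = 0.35) {
  texture <- match.arg(texture)
  td <- texture_defaults(texture)
  cfg <- list(
    seed = as.integer(seed),
    season_rain_total = season_rain_total,
    season_days = as.integer(season_days),
    texture = texture,
    background_cl = background_cl,
    cl_doses = sort(unique(cl_doses)),
    noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    sampling_rain = sampling_rain,
    plant_uptake = plant_uptake,
    background_decay = background_decay,
    bulk_density = if (is.null(bulk_density)) td$bulk_density else bulk_density,
    clay = if (is.null(clay)) td$clay else clay,
    pulse_velocity = if (is.null(pulse_velocity)) td$pulse_velocity else pulse_velocity,
    pulse_spread = pulse_spread,
    eff_rain = if (is.null(eff_rain)) td$eff_rain else eff_rain,
    eff_frac = if (is.null(eff_frac)) td$eff_frac else eff_frac,
    dose_sensitivity = dose_sensitivity,
    ck_yield = ck_yield,
    yield_cv = yield_cv,
    so4_background = so4_background,
    early_heavy_prob = early_heavy_prob,
    ry_bounds = td$ry_bounds)
  if (cfg$season_rain_total <= 0) stop("season_rain_total must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$background_cl < 0) stop("background_cl must be non-negative")
  if (any(diff(cfg$eff_rain) <= 0) || any(diff(cfg$eff_frac) < 0))
    stop("efficiency anchors must be monotone")
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic trial config: %s, %g mm season, doses %s kg/ha, seed %d\n",
              x$texture, x$season_rain_total,
              paste(x$cl_doses, collapse = "/"), x$seed))
  invisible(x)
}

## True leaching efficiency (fraction of the dose leached below 45 cm) at a
## cumulative rainfall, with a mild dose dependence. Monotone spline through
## the calibration anchors, clamped beyond the last anchor.
true_efficiency <- function(config, rain, dose = 75) {
  f <- stats::splinefun(config$eff_rain, config$eff_frac, method = "hyman")
  base <- f(pmin(pmax(rain, 0), max(config$eff_rain)))
  mult <- 1 + config$dose_sensitivity * (dose - 75)
  pmin(pmax(base * mult, 0), 0.97)
}

## Fractions of the residual (not-yet-leached) exogenous stock per layer,
## from the Gaussian depth pulse truncated to the 0-45 cm profile.
true_layer_weights <- function(config, rain) {
  centre <- 7.5 + config$pulse_velocity * rain
  spread <- config$pulse_spread[1] + config$pulse_spread[2] * rain
  bounds <- c(0, 15, 30, 45)
  p <- stats::pnorm(bounds, mean = centre, sd = spread)
  w <- diff(p)
  w / sum(w)
}

## Exogenous Cl- stock (kg/ha) per layer for one dose at one rainfall.
true_layer_stocks <- function(config, rain, dose) {
  residual <- dose * (1 - true_efficiency(config, rain, dose))
  residual * true_layer_weights(config, rain)
}

#' Generate a daily rainfall series
#'
#' Wet days carry event sizes drawn from a light/heavy gamma mixture (light
#' rain about 2 mm, heavy events about 14 mm); the probability that a wet day
#' in the first third of the season is heavy is configurable, emulating
#' seasons with early convective storms. The series is scaled so its sum
#' equals `season_rain_total` exactly, which preserves the wet-day pattern:
#' two totals at the same seed differ by a pointwise scale factor.
#'
#' @param config a [generator_config()].
#' @return a data frame with columns `day` and `rain_mm`.
#' @export
generate_rainfall <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  on.exit(restore_rng()())
  set.seed(config$seed)
  nd <- config$season_days
  wet <- stats::runif(nd) < 0.45
  early <- seq_len(nd) <= nd / 3
  heavy_prob <- ifelse(early, config$early_heavy_prob, 0.20)
  heavy <- wet & (stats::runif(nd) < heavy_prob)
  amt <- numeric(nd)
  amt[wet & !heavy] <- stats::rgamma(sum(wet & !heavy), shape = 1.2, scale = 2.2 / 1.2)
  amt[heavy] <- stats::rgamma(sum(heavy), shape = 2, scale = 14 / 2)
  amt <- amt * config$season_rain_total / sum(amt)
  data.frame(day = seq_len(nd), rain_mm = amt)
}

sampling_schedule <- function(config, rainfall) {
  cum <- cumsum(rainfall$rain_mm)
  keep <- config$sampling_rain <= cum[length(cum)] + 1e-9
  milestones <- config$sampling_rain[keep]
  das <- vapply(milestones, function(m) which(cum >= m - 1e-9)[1], integer(1))
  data.frame(das = das, cum_rain = milestones)
}

#' Generate layer-wise chloride profile observations
#'
#' Produces the long-format observation table of a synthetic trial. Treated
#' concentrations are the (rain-declining) background plus the residual
#' exogenous pulse converted to mg/kg; controls carry background only.
#' Gaussian noise of `noise_sd` mg/kg is added and results floored at 0. Sampling occurs at the
#' cumulative-rainfall milestones of the config; sampling days are derived
#' from the generated rainfall series.
#'
#' @param config a [generator_config()].
#' @param rainfall optional rainfall series from [generate_rainfall()];
#'   regenerated from the config when omitted.
#' @return a data frame with columns `site_id`, `texture`, `treatment`
#'   (CK/L/M/H by increasing dose), `replicate`, `das`, `cum_rain_mm`,
#'   `layer_top_cm`, `layer_bottom_cm`, `cl_mgkg`, `so4_mgkg`; the generating
#'   truth is attached as attribute `"truth"`.
#' @export
generate_profile_timeseries <- function(config, rainfall = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(rainfall)) rainfall <- generate_rainfall(config)
  sched <- sampling_schedule(config, rainfall)
  if (!nrow(sched))
    stop("no sampling milestone lies within the season's rainfall", call. = FALSE)
  doses <- config$cl_doses
  labels <- treatment_labels(doses)
  layers <- data.frame(top = c(0, 15, 30), bottom = c(15, 30, 45))
  grid <- expand.grid(layer = seq_len(3), rep = seq_len(config$n_replicates),
                      date = seq_len(nrow(sched)), dose_i = seq_along(doses))
  soil_mass <- config$bulk_density * 15 * 0.1   # kg/ha stock per mg/kg
  exo <- mapply(function(di, dt, ly) {
    d <- doses[di]
    if (d == 0) return(0)
    true_layer_stocks(config, sched$cum_rain[dt], d)[ly] / soil_mass
  }, grid$dose_i, grid$date, grid$layer)
  on.exit(restore_rng()())
  set.seed(config$seed + 1L)
  noise <- stats::rnorm(nrow(grid), 0, config$noise_sd)
  so4_noise <- stats::rnorm(nrow(grid), 0, config$noise_sd)
  bg <- config$background_cl *
    exp(-sched$cum_rain[grid$date] / config$background_decay)
  cl <- pmax(bg + exo + noise, 0)
  so4 <- pmax(config$so4_background *
                exp(-sched$cum_rain[grid$date] / 400) + so4_noise, 0)
  out <- data.frame(
    site_id = if (config$texture == "loam") "site_loam" else "site_sandy",
    texture = config$texture,
    treatment = labels[grid$dose_i],
    replicate = grid$rep,
    das = sched$das[grid$date],
    cum_rain_mm = sched$cum_rain[grid$date],
    layer_top_cm = layers$top[grid$layer],
    layer_bottom_cm = layers$bottom[grid$layer],
    cl_mgkg = cl,
    so4_mgkg = so4,
    stringsAsFactors = FALSE)
  out <- out[order(out$das, out$treatment, out$replicate, out$layer_top_cm), ]
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    background = function(rain)
      config$background_cl * exp(-rain / config$background_decay),
    efficiency = function(rain, dose) true_efficiency(config, rain, dose),
    layer_weights = function(rain) true_layer_weights(config, rain),
    layer_stocks = function(rain, dose) true_layer_stocks(config, rain, dose),
    schedule = sched, config = config)
  out
}

treatment_labels <- function(doses) {
  nz <- sort(doses[doses > 0])
  lab <- character(length(doses))
  std <- c("L", "M", "H")
  for (i in seq_along(doses)) {
    if (doses[i] == 0) lab[i] <- "CK"
    else {
      k <- match(doses[i], nz)
      lab[i] <- if (length(nz) <= 3) std[k] else paste0("D", k)
    }
  }
  lab
}

#' Default relative-yield curve of a texture
#'
#' The generator's yield truth: a concave quadratic `RY(d)` anchored at
#' `RY(0) = 100` whose descending limb crosses 100 % and 95 % at the
#' texture's reference dose bounds (51.6 and 73.8 kg Cl/ha in loam; 96.3 and
#' 106.8 in sandy loam).
#'
#' @param config a [generator_config()], or a texture name.
#' @return a list with `p0`, `p1`, `p2` (percent vs kg Cl/ha).
#' @export
default_yield_curve <- function(config) {
  b <- if (inherits(config, "generator_config")) config$ry_bounds
       else texture_defaults(config)$ry_bounds
  d100 <- b[["ry100"]]; d95 <- b[["ry95"]]
  p2 <- -5 / (d95 * (d95 - d100))
  list(p0 = 100, p1 = -d100 * p2, p2 = p2)
}

#' Generate replicate tuber yields under a dose-response truth
#'
#' Yields are `ck_yield * RY(dose)/100 * (1 + N(0, cv))` per replicate.
#'
#' @param config a [generator_config()].
#' @param curve yield-curve truth: a list with `p0`, `p1`, `p2` (default the
#'   texture's [default_yield_curve()]), or a [fit_dose_response()] object.
#' @param cv replicate coefficient of variation; default `config$yield_cv`.
#' @return data frame with columns `dose`, `replicate`, `yield_t_ha`,
#'   `ry_true`; the truth curve is attached as attribute `"truth"`.
#' @export
generate_yield <- function(config, curve = default_yield_curve(config),
                           cv = config$yield_cv) {
  stopifnot(inherits(config, "generator_config"))
  if (inherits(curve, "dose_response"))
    curve <- list(p0 = curve$p0, p1 = curve$p1, p2 = curve$p2)
  if (!is.finite(curve$p2) || curve$p2 >= 0)
    stop("yield curve must be concave (p2 < 0)", call. = FALSE)
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  doses <- config$cl_doses
  grid <- expand.grid(replicate = seq_len(config$n_replicates), dose = doses)
  ry <- curve$p0 + curve$p1 * grid$dose + curve$p2 * grid$dose^2
  on.exit(restore_rng()())
  set.seed(config$seed + 2L)
  mult <- 1 + stats::rnorm(nrow(grid), 0, cv)
  out <- data.frame(dose = grid$dose, replicate = grid$replicate,
                    yield_t_ha = config$ck_yield * ry / 100 * mult,
                    ry_true = ry)
  attr(out, "truth") <- curve
  out
}

#' Simulate a complete synthetic field trial
#'
#' Bundles rainfall, profile observations and yields for one site/season,
#' retaining the generating truth so estimates can be compared against it.
#'
#' @param config a [generator_config()].
#' @return an object of class `synthetic_trial`: list with `rainfall`,
#'   `observations`, `yields`, `truth`, `config`.
#' @export
#' @examples
#' tr <- simulate_trial(generator_config(seed = 42))
#' head(tr$observations)
simulate_trial <- function(config = generator_config()) {
  rainfall <- generate_rainfall(config)
  obs <- generate_profile_timeseries(config, rainfall)
  yields <- generate_yield(config)
  structure(
    list(rainfall = rainfall,
         observations = obs,
         yields = yields,
         truth = attr(obs, "truth"),
         config = config),
    class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic %s trial: %d observations, %d sampling dates, %g mm rain\n",
              x$config$texture, nrow(x$observations),
              nrow(x$truth$schedule), x$config$season_rain_total))
  invisible(x)
}
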