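## Rainfall-response curve fitting, leaching-efficiency series, critical
## rainfall solving, and layer-distribution summaries.

#' Published rainfall-response coefficients
#'
#' The quadratic fits `y = a*x^2 + b*x + c` of layer Cl- content (mg/kg)
#' against cumulative rainfall (mm), per texture, dose level and soil layer,
#' together with the linear Pearson correlation between rainfall and content.
#' These are the reference coefficients used as oracles in recovery tests and
#' as worked examples; the synthetic trial generator uses a mass-conserving
#' pulse mechanism instead (see [generator_config()]).
#'
#' @return a data frame with columns `texture`, `dose_level` (L/M/H),
#'   `layer_top`, `layer_bottom`, `a`, `b`, `c`, `pearson_r`.
#' @export
#' @examples
#' head(cl_response_table())
cl_response_table <- function() {
  tex <- rep(c("loam", "sandy_loam"), each = 9)
  lev <- rep(rep(c("L", "M", "H"), each = 3), 2)
  top <- rep(c(0, 15, 30), 6)
  data.frame(
    texture = tex, dose_level = lev,
    layer_top = top, layer_bottom = top + 15,
    a = c( 4.55e-4,  8.31e-4, -7.68e-4,
           1.51e-3, -1.28e-3, -1.37e-3,
           1.08e-3, -1.93e-3, -2.04e-3,
           6.55e-4,  2.04e-4, -7.25e-5,
           8.49e-4,  6.68e-5, -3.47e-4,
           1.01e-3,  2.94e-5, -6.03e-4),
    b = c(-0.27, -0.39,  0.16,
          -0.61,  0.32,  0.35,
          -0.49,  0.31,  0.52,
          -0.32, -0.19, -0.02,
          -0.44, -0.16,  0.05,
          -0.53, -0.19,  0.13),
    c = c(41.93, 50.70, 15.55,
          66.42,  8.55, 11.42,
          64.34, 47.98, 11.19,
          44.09, 44.10, 20.03,
          61.21, 48.25, 26.95,
          74.73, 61.06, 27.72),
    pearson_r = c(-0.823, -0.704, -0.318,
                  -0.800, -0.650, -0.342,
                  -0.727, -0.644, -0.131,
                  -0.785, -0.755, -0.650,
                  -0.829, -0.750, -0.636,
                  -0.836, -0.793, -0.674),
    stringsAsFactors = FALSE)
}

#' Fit a quadratic rainfall-response curve
#'
#' Least-squares fit of `conc = a*rain^2 + b*rain + c`, plus the linear
#' Pearson correlation between rainfall and content (the conventional "r"
#' reported alongside such fits, which is negative for declining contents
#' even when the quadratic opens upward, and therefore is not the fit's own
#' correlation).
#'
#' @param rain cumulative rainfall values, mm (at least 4 distinct).
#' @param conc Cl- contents, mg/kg.
#' @return an object of class `quad_response` with elements `a`, `b`, `c`,
#'   `pearson_r`, `rain_range` and the `lm` fit.
#' @export
#' @examples
#' r <- seq(0, 300, 30)
#' f <- fit_quadratic_response(r, 4.55e-4 * r^2 - 0.27 * r + 41.93)
#' c(f$a, f$b, f$c)
fit_quadratic_response <- function(rain, conc) {
  check_finite(rain, "rain")
  check_finite(conc, "conc")
  if (length(rain) != length(conc))
    stop("'rain' and 'conc' must have equal length", call. = FALSE)
  if (length(unique(rain)) < 4)
    stop("insufficient data: at least 4 distinct rainfall values", call. = FALSE)
  fit <- stats::lm(conc ~ rain + I(rain^2))
  cf <- stats::coef(fit)
  structure(
    list(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]),
         pearson_r = stats::cor(rain, conc),
         rain_range = range(rain), fit = fit),
    class = "quad_response")
}

#' @export
print.quad_response <- function(x, ...) {
  cat(sprintf("Quadratic rainfall response: y = %.4g*x^2 %+.4g*x %+.4g\n",
              x$a, x$b, x$c))
  cat(sprintf("  Pearson r(rain, conc) = %.3f; fitted on rain in [%g, %g] mm\n",
              x$pearson_r, x$rain_range[1], x$rain_range[2]))
  invisible(x)
}

#' @export
predict.quad_response <- function(object, rain, ...) {
  check_finite(rain, "rain")
  object$a * rain^2 + object$b * rain + object$c
}

#' Leaching-efficiency series from chloride budgets
#'
#' The leaching efficiency at a sampling date is the leaching factor of the
#' 0-45 cm profile at that date. Budgets must belong to one treatment and be
#' ordered by strictly increasing cumulative rainfall. Noise can make
#' efficiency non-monotone or push it outside `[0, 1]`; such points are
#' flagged, not dropped.
#'
#' @param budgets a list of [cl_budget()] objects with `cum_rain` set.
#' @return a data frame with columns `cum_rain`, `efficiency`, `out_of_range`
#'   (logical); a `"flag"` attribute `"non_monotone"` is set when efficiency
#'   decreases between successive dates.
#' @export
efficiency_series <- function(budgets) {
  if (!length(budgets)) stop("empty budget list", call. = FALSE)
  if (inherits(budgets, "cl_budget")) budgets <- list(budgets)
  rain <- vapply(budgets, function(b) as.numeric(b$cum_rain), numeric(1))
  if (any(!is.finite(rain)))
    stop("all budgets must carry 'cum_rain'", call. = FALSE)
  if (any(diff(rain) <= 0))
    stop("'cum_rain' must be strictly increasing across budgets", call. = FALSE)
  eff <- vapply(budgets, function(b) b$leaching_factor, numeric(1))
  out <- data.frame(cum_rain = rain, efficiency = eff,
                    out_of_range = eff < 0 | eff > 1)
  if (any(diff(eff) < 0)) attr(out, "flag") <- "non_monotone"
  out
}

#' Critical rainfall for a target leaching efficiency
#'
#' Fits a straight line `efficiency = alpha + beta * rain` by least squares
#' to an efficiency series and solves for the rainfall at which the target
#' efficiency is reached. Points with efficiency outside `[0, 1]` are
#' excluded from the fit by default (they arise from measurement noise).
#' A solution beyond 1.25 times the largest observed rainfall is flagged
#' `"extrapolation"` but still returned.
#'
#' @param points a data frame with columns `cum_rain` and `efficiency`
#'   (as from [efficiency_series()]); at least 3 points.
#' @param target target efficiency, a fraction in (0, 1).
#' @param include_out_of_range include efficiency values outside `[0, 1]`
#'   in the line fit (default `FALSE`).
#' @return critical rainfall in mm, with attributes `alpha`, `beta` and
#'   possibly a `"flag"`.
#' @export
#' @examples
#' pts <- data.frame(cum_rain = c(50, 100, 150), efficiency = 0.003 * c(50, 100, 150))
#' critical_rainfall(pts, 0.30)   # 100 mm
critical_rainfall <- function(points, target, include_out_of_range = FALSE) {
  if (!all(c("cum_rain", "efficiency") %in% names(points)))
    stop("'points' needs columns cum_rain and efficiency", call. = FALSE)
  if (target < 0 || target >= 1)
    stop("'target' must be a fraction in [0, 1)", call. = FALSE)
  pts <- points
  if (!include_out_of_range)
    pts <- pts[pts$efficiency >= 0 & pts$efficiency <= 1, , drop = FALSE]
  if (nrow(pts) < 3)
    stop("insufficient data: at least 3 usable points", call. = FALSE)
  fit <- stats::lm(efficiency ~ cum_rain, data = pts)
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  if (beta <= 0)
    stop("no leaching trend: fitted slope is not positive", call. = FALSE)
  rain <- (target - alpha) / beta
  fl <- NULL
  if (rain > 1.25 * max(points$cum_rain)) fl <- "extrapolation"
  if (rain < 0) {
    rain <- 0
    fl <- c(fl, "already_above_target")
  }
  out <- flag_value(rain, fl)
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  out
}

#' Layer distribution of chloride stocks
#'
#' Normalises per-layer stocks into fractions of the profile total.
#'
#' @param stocks numeric vector of per-layer stocks (kg/ha), named or ordered
#'   top to bottom; must contain at least one positive value.
#' @param milestone_rain optional cumulative rainfall (mm) the distribution
#'   refers to, carried through for reporting.
#' @return an object of class `layer_distribution`: list with `fractions`
#'   (summing to 1), `stocks`, `milestone_rain`.
#' @export
#' @examples
#' layer_distribution(c(`0-15` = 85, `15-30` = 10, `30-45` = 5), 20)
layer_distribution <- function(stocks, milestone_rain = NA_real_) {
  check_nonneg(stocks, "stocks")
  tot <- sum(stocks)
  if (tot <= 0)
    stop("undefined distribution: all layer stocks are zero", call. = FALSE)
  structure(
    list(fractions = stocks / tot, stocks = stocks,
         milestone_rain = milestone_rain),
    class = "layer_distribution")
}

#' @export
print.layer_distribution <- function(x, ...) {
  cat("Layer distribution of Cl- stock")
  if (is.finite(x$milestone_rain))
    cat(sprintf(" at %.0f mm cumulative rain", x$milestone_rain))
  cat("\n")
  f <- x$fractions
  nm <- if (is.null(names(f))) paste("layer", seq_along(f)) else names(f)
  for (i in seq_along(f))
    cat(sprintf("  %-8s %5.1f %%\n", nm[i], 100 * f[i]))
  invisible(x)
}
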