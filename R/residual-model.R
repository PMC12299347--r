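## The residual chloride estimation model: an affine model in cumulative
## rainfall (mm), chloride application rate (kg/ha) and soil clay content (%),
## its two practical inversions, and OLS refitting.

#' Residual soil chloride estimation model
#'
#' Constructs the three-covariate linear model for residual water-soluble
#' chloride (mg/kg) in the 0-45 cm profile:
#' `Y = intercept + slope_rain * rainfall + slope_cl * cl_rate + slope_clay * clay`.
#' The default coefficients are the published calibration
#' (38.518, -0.219, +0.143, +0.557). A model is considered sign-consistent
#' when the rainfall slope is negative and the dose and clay slopes positive;
#' violation is flagged, not an error, since refitted models may differ.
#'
#' @param intercept intercept, mg/kg.
#' @param slope_rain coefficient of cumulative rainfall, mg/kg per mm.
#' @param slope_cl coefficient of chloride application rate, mg/kg per kg/ha.
#' @param slope_clay coefficient of clay content, mg/kg per %.
#' @param se optional named numeric vector of coefficient standard errors.
#' @return an object of class `cl_residual_model`.
#' @seealso [predict.cl_residual_model()], [required_rainfall()],
#'   [allowable_cl_dose()], [fit_residual_model()]
#' @export
#' @examples
#' m <- cl_residual_model()
#' coef(m)
#' predict(m, rainfall = 100, cl_rate = 37.5, clay = 9.8)
cl_residual_model <- function(intercept = 38.518, slope_rain = -0.219,
                              slope_cl = 0.143, slope_clay = 0.557,
                              se = NULL) {
  cf <- c(intercept = intercept, slope_rain = slope_rain,
          slope_cl = slope_cl, slope_clay = slope_clay)
  check_finite(cf, "coefficients")
  obj <- structure(
    list(coefficients = cf, se = se,
         clay_envelope = c(9.8, 12.9)),
    class = "cl_residual_model")
  if (!(slope_rain < 0 && slope_cl > 0 && slope_clay > 0))
    attr(obj, "flag") <- "sign_inconsistent"
  obj
}

#' @export
coef.cl_residual_model <- function(object, ...) object$coefficients

#' @export
print.cl_residual_model <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Residual soil Cl- estimation model (mg/kg)\n")
  cat(sprintf("  Y = %.3f %+.3f*rainfall[mm] %+.3f*cl_rate[kg/ha] %+.3f*clay[%%]\n",
              cf[1], cf[2], cf[3], cf[4]))
  if (!is.null(x$se)) {
    cat("  standard errors:\n")
    print(round(x$se, digits))
  }
  if (!is.null(flags(x))) cat("  flags:", paste(flags(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cl_residual_model <- function(object, ...) {
  cf <- object$coefficients
  tab <- cbind(Estimate = cf,
               `Std. Error` = if (is.null(object$se)) rep(NA_real_, 4)
                              else object$se[names(cf)])
  structure(list(coefficients = tab, fit = object$fit), class = "summary.cl_residual_model")
}

#' @export
print.summary.cl_residual_model <- function(x, ...) {
  cat("Residual Cl- model coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

check_model_input <- function(rainfall, cl_rate, clay) {
  check_nonneg(rainfall, "rainfall")
  check_nonneg(cl_rate, "cl_rate")
  check_finite(clay, "clay")
  if (any(clay < 0 | clay > 100))
    stop("'clay' must be a percentage in [0, 100]", call. = FALSE)
  invisible(NULL)
}

#' Predict residual soil chloride
#'
#' Evaluates the affine model. Negative raw predictions (large rainfall, low
#' dose) are interpreted as "fully leached", clamped to 0 mg/kg and flagged
#' `"clamped"`. Clay contents outside the calibration envelope (9.8-12.9 %)
#' are flagged `"extrapolation"`.
#'
#' @param object a [cl_residual_model()].
#' @param rainfall cumulative rainfall since basal application, mm.
#' @param cl_rate chloride application rate, kg/ha.
#' @param clay soil clay content, %.
#' @param clamp clamp negative predictions at 0 (default `TRUE`).
#' @param ... unused.
#' @return predicted residual Cl- in mg/kg (vectorised), with a `"flag"`
#'   attribute when clamping or extrapolation occurred.
#' @export
predict.cl_residual_model <- function(object, rainfall, cl_rate, clay,
                                      clamp = TRUE, ...) {
  check_model_input(rainfall, cl_rate, clay)
  cf <- object$coefficients
  y <- cf[["intercept"]] + cf[["slope_rain"]] * rainfall +
    cf[["slope_cl"]] * cl_rate + cf[["slope_clay"]] * clay
  fl <- character()
  if (any(clay < object$clay_envelope[1] | clay > object$clay_envelope[2]))
    fl <- c(fl, "extrapolation")
  if (clamp && any(y < 0)) {
    y <- pmax(y, 0)
    fl <- c(fl, "clamped")
  }
  flag_value(y, fl)
}

#' Rainfall required to reach a target residual chloride content
#'
#' Inverts the model for its rainfall covariate: the cumulative rainfall at
#' which the predicted residual content equals `target_cl` for a given dose
#' and clay content. Negative solutions mean the profile is already below the
#' target at zero rainfall; 0 is returned with flag `"already_below_target"`.
#'
#' @param model a [cl_residual_model()].
#' @param target_cl target residual Cl- content, mg/kg.
#' @param cl_rate chloride application rate, kg/ha.
#' @param clay soil clay content, %.
#' @return required rainfall in mm (vectorised).
#' @export
#' @examples
#' required_rainfall(cl_residual_model(), target_cl = 20,
#'                   cl_rate = 75, clay = 12.9)   # about 166 mm
required_rainfall <- function(model, target_cl, cl_rate, clay) {
  check_nonneg(target_cl, "target_cl")
  check_model_input(0, cl_rate, clay)
  cf <- model$coefficients
  if (cf[["slope_rain"]] == 0)
    stop("degenerate model: rainfall slope is zero", call. = FALSE)
  x1 <- (cf[["intercept"]] + cf[["slope_cl"]] * cl_rate +
           cf[["slope_clay"]] * clay - target_cl) / (-cf[["slope_rain"]])
  if (any(x1 < 0)) {
    x1 <- pmax(x1, 0)
    x1 <- flag_value(x1, "already_below_target")
  }
  x1
}

#' Allowable chloride dose under a given rainfall
#'
#' Inverts the model for its dose covariate: the chloride application rate at
#' which the predicted residual content equals `target_cl` under a given
#' cumulative rainfall and clay content. Negative solutions mean the target
#' is below the zero-dose prediction; 0 is returned with flag
#' `"target_unreachable_at_zero_dose"`.
#'
#' @param model a [cl_residual_model()].
#' @param target_cl target residual Cl- content, mg/kg.
#' @param rainfall cumulative rainfall, mm.
#' @param clay soil clay content, %.
#' @return allowable dose in kg Cl/ha (vectorised).
#' @export
allowable_cl_dose <- function(model, target_cl, rainfall, clay) {
  check_nonneg(target_cl, "target_cl")
  check_model_input(rainfall, 0, clay)
  cf <- model$coefficients
  if (cf[["slope_cl"]] == 0)
    stop("degenerate model: dose slope is zero", call. = FALSE)
  x2 <- (target_cl - cf[["intercept"]] - cf[["slope_rain"]] * rainfall -
           cf[["slope_clay"]] * clay) / cf[["slope_cl"]]
  if (any(x2 < 0)) {
    x2 <- pmax(x2, 0)
    x2 <- flag_value(x2, "target_unreachable_at_zero_dose")
  }
  x2
}

#' Refit the residual model to observations by ordinary least squares
#'
#' Recalibrates the four coefficients against measured residual chloride
#' contents. The design must contain at least 5 observations and be full
#' rank: with a single clay value (or any collinear pair of columns) the
#' normal equations are singular and an error names the offending columns.
#'
#' @param data a data frame with columns `rainfall` (mm), `cl_rate` (kg/ha),
#'   `clay` (%) and `measured` (mg/kg).
#' @return a [cl_residual_model()] with standard errors in `$se` and the
#'   underlying [stats::lm] fit in `$fit`.
#' @export
#' @examples
#' g <- expand.grid(rainfall = seq(0, 300, 50),
#'                  cl_rate = c(0, 37.5, 75, 112.5), clay = c(9.8, 12.9))
#' g$measured <- predict(cl_residual_model(), g$rainfall, g$cl_rate, g$clay,
#'                       clamp = FALSE)
#' coef(fit_residual_model(g))
fit_residual_model <- function(data) {
  req <- c("rainfall", "cl_rate", "clay", "measured")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(data) < 5)
    stop("at least 5 observations are required", call. = FALSE)
  X <- cbind(intercept = 1, slope_rain = data$rainfall,
             slope_cl = data$cl_rate, slope_clay = data$clay)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(measured ~ rainfall + cl_rate + clay, data = data)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  names(cf) <- names(se) <- c("intercept", "slope_rain", "slope_cl", "slope_clay")
  out <- cl_residual_model(cf[["intercept"]], cf[["slope_rain"]],
                           cf[["slope_cl"]], cf[["slope_clay"]], se = se)
  out$fit <- fit
  out
}
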