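## Relative-yield analysis: quadratic dose-response fitting, safe KCl range
## solving and toxicity classification.

#' Relative tuber yield
#'
#' Treated-plot yield as a percentage of the control yield.
#'
#' @param treated yield under a chloride treatment, t/ha.
#' @param control yield under the no-chloride control, t/ha; must be positive.
#' @return relative yield in percent.
#' @export
relative_yield <- function(treated, control) {
  check_nonneg(treated, "treated")
  check_finite(control, "control")
  if (any(control <= 0))
    stop("'control' yield must be positive", call. = FALSE)
  100 * treated / control
}

#' Fit a quadratic dose-response curve for relative yield
#'
#' Least-squares fit of `RY(d) = p0 + p1*d + p2*d^2` to relative-yield
#' observations over chloride doses. A concave curve (`p2 < 0`) has an
#' optimum at `-p1 / (2*p2)`; tuber yield typically first rises then falls
#' with dose. A non-concave fit is returned with a warning flag since no
#' safe range exists on it.
#'
#' @param dose chloride application rates, kg Cl/ha; at least 4 distinct
#'   values including 0 (the control anchor).
#' @param relative_yield relative yields, percent.
#' @return an object of class `dose_response` with coefficients `p0`, `p1`,
#'   `p2`, the `optimum_dose` and `ry_at_optimum` (NA when `p2 >= 0`), and
#'   the underlying `lm` fit.
#' @export
#' @examples
#' d <- c(0, 25, 50, 75, 100)
#' fit_dose_response(d, 100 + 0.05 * d - 0.001 * d^2)
fit_dose_response <- function(dose, relative_yield) {
  check_nonneg(dose, "dose")
  check_finite(relative_yield, "relative_yield")
  if (length(dose) != length(relative_yield))
    stop("'dose' and 'relative_yield' must have equal length", call. = FALSE)
  if (length(unique(dose)) < 4)
    stop("insufficient data: at least 4 distinct doses", call. = FALSE)
  if (!any(dose == 0))
    stop("the zero-dose control must be included", call. = FALSE)
  fit <- stats::lm(relative_yield ~ dose + I(dose^2))
  cf <- stats::coef(fit)
  p0 <- unname(cf[1]); p1 <- unname(cf[2]); p2 <- unname(cf[3])
  concave <- is.finite(p2) && p2 < 0
  opt <- if (concave) -p1 / (2 * p2) else NA_real_
  out <- structure(
    list(p0 = p0, p1 = p1, p2 = p2,
         optimum_dose = opt,
         ry_at_optimum = if (concave) p0 + p1 * opt + p2 * opt^2 else NA_real_,
         fit = fit),
    class = "dose_response")
  if (!concave) {
    warning("no descending limb (p2 >= 0); safe range undefined", call. = FALSE)
    attr(out, "flag") <- "no_descending_limb"
  }
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response: RY(d) = %.4g %+.4g*d %+.4g*d^2  [%% vs kg Cl/ha]\n",
              x$p0, x$p1, x$p2))
  if (is.finite(x$optimum_dose))
    cat(sprintf("  optimum %.1f kg Cl/ha (RY %.1f %%)\n",
                x$optimum_dose, x$ry_at_optimum))
  if (!is.null(flags(x))) cat("  flags:", paste(flags(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.dose_response <- function(object, dose, ...) {
  check_finite(dose, "dose")
  object$p0 + object$p1 * dose + object$p2 * dose^2
}

#' Safe chloride / KCl application range from a dose-response fit
#'
#' Solves `RY(d) = 100` and `RY(d) = 95` on the descending limb of a concave
#' dose-response curve (roots above the optimum). Doses are converted to KCl
#' equivalents by dividing by the Cl mass fraction of KCl (0.45). When the
#' curve never reaches 100 % for positive doses, only the 95 % bound is
#' returned, flagged `"ry100_unreachable"`.
#'
#' @param fit a [fit_dose_response()] object with `p2 < 0`.
#' @param kcl_cl_fraction Cl mass fraction of KCl (default 0.45).
#' @return an object of class `safe_range`: list with `dose_ry100`,
#'   `dose_ry95` (kg Cl/ha), `kcl_ry100`, `kcl_ry95` (kg KCl/ha).
#' @export
#' @examples
#' f <- fit_dose_response(c(0, 25, 50, 75, 100),
#'                        100 + 0.05 * c(0, 25, 50, 75, 100) -
#'                          0.001 * c(0, 25, 50, 75, 100)^2)
#' safe_dose_range(f)   # Cl 50-100, KCl 111-222 kg/ha
safe_dose_range <- function(fit, kcl_cl_fraction = 0.45) {
  if (!inherits(fit, "dose_response"))
    stop("'fit' must be a dose_response object", call. = FALSE)
  if (!is.finite(fit$p2) || fit$p2 >= 0)
    stop("no descending limb: p2 must be negative", call. = FALSE)
  upper_root <- function(target) {
    # p2 d^2 + p1 d + (p0 - target) = 0; descending-limb root is the larger one
    disc <- fit$p1^2 - 4 * fit$p2 * (fit$p0 - target)
    if (disc < 0) return(NA_real_)
    (-fit$p1 - sqrt(disc)) / (2 * fit$p2)   # p2 < 0 so this is the larger root
  }
  d100 <- upper_root(100)
  d95 <- upper_root(95)
  fl <- NULL
  if (!is.finite(d100) || d100 <= 0) {
    d100 <- NA_real_
    fl <- "ry100_unreachable"
  }
  if (!is.finite(d95))
    stop("curve never reaches 95 % relative yield", call. = FALSE)
  out <- structure(
    list(dose_ry100 = d100, dose_ry95 = d95,
         kcl_ry100 = d100 / kcl_cl_fraction,
         kcl_ry95 = d95 / kcl_cl_fraction,
         kcl_cl_fraction = kcl_cl_fraction),
    class = "safe_range")
  if (!is.null(fl)) attr(out, "flag") <- fl
  out
}

#' @export
print.safe_range <- function(x, ...) {
  cat("Safe chloride application range (descending limb)\n")
  cat(sprintf("  RY 100 %%: %6.1f kg Cl/ha  = %6.0f kg KCl/ha\n",
              x$dose_ry100, x$kcl_ry100))
  cat(sprintf("  RY  95 %%: %6.1f kg Cl/ha  = %6.0f kg KCl/ha\n",
              x$dose_ry95, x$kcl_ry95))
  if (!is.null(flags(x))) cat("  flags:", paste(flags(x), collapse = ", "), "\n")
  invisible(x)
}

#' Classify chloride toxicity from relative yield
#'
#' Bands: above 100 % no suppression, 95-100 % safe, 80-90 % mild toxicity,
#' below 50 % severe. The published rubric leaves 90-95 % and 50-80 %
#' undefined; they are gap-filled as `"marginal"` and `"moderate"` and
#' flagged as interpolation beyond the rubric.
#'
#' @param relative_yield relative yield in percent (scalar or vector).
#' @return character vector of classes among `no_suppression`, `safe`,
#'   `marginal`, `mild`, `moderate`, `severe`; a `"flag"` attribute
#'   `"gap_filled"` marks results using the interpolated bands.
#' @export
#' @examples
#' classify_toxicity(c(101, 97, 85, 45))
classify_toxicity <- function(relative_yield) {
  check_nonneg(relative_yield, "relative_yield")
  cls <- ifelse(relative_yield > 100, "no_suppression",
         ifelse(relative_yield >= 95, "safe",
         ifelse(relative_yield >= 90, "marginal",
         ifelse(relative_yield >= 80, "mild",
         ifelse(relative_yield >= 50, "moderate", "severe")))))
  if (any(cls %in% c("marginal", "moderate")))
    cls <- flag_value(cls, "gap_filled")
  cls
}
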