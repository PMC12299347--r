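## Model-evaluation suite: Pearson r, R2, RMSE, NRMSE, PBIAS, and the
## banded goodness-of-fit rubric.

#' Goodness-of-fit metrics between measured and modelled series
#'
#' Computes the standard agro-hydrological validation suite for a paired
#' series of measured and model-calculated values:
#' \describe{
#'   \item{r}{Pearson correlation between measured and modelled.}
#'   \item{r2}{coefficient of determination,
#'     `1 - sum((modeled - measured)^2) / sum((mean(measured) - measured)^2)`.
#'     Unlike `r^2`, this compares the model to the measured mean, so it can
#'     be negative for a poor model.}
#'   \item{rmse}{root mean square error, same units as the series.}
#'   \item{nrmse}{RMSE normalised by the observed range
#'     `max(measured) - min(measured)` (not by the mean).}
#'   \item{pbias}{percentage bias,
#'     `sum(measured - modeled) / sum(measured) * 100`; positive values mean
#'     the model under-predicts on aggregate.}
#' }
#'
#' @param measured numeric vector of measured values (length >= 3).
#' @param modeled numeric vector of model-calculated values, same length.
#' @return an object of class `cl_validation`: a list with the five metrics,
#'   `n`, and `gfi_labels` from [classify_gfi()].
#' @export
#' @examples
#' compute_metrics(c(10, 20, 30), c(12, 18, 33))
compute_metrics <- function(measured, modeled) {
  check_finite(measured, "measured")
  check_finite(modeled, "modeled")
  n <- length(measured)
  if (length(modeled) != n)
    stop("'measured' and 'modeled' must have equal length", call. = FALSE)
  if (n < 3)
    stop("insufficient data: at least 3 pairs are required", call. = FALSE)
  rng <- max(measured) - min(measured)
  if (rng <= 0)
    stop("NRMSE undefined: 'measured' series is constant", call. = FALSE)
  err <- measured - modeled
  sse <- sum(err^2)
  sst <- sum((mean(measured) - measured)^2)
  rmse <- sqrt(sse / n)
  rep <- structure(
    list(r = stats::cor(measured, modeled),
         r2 = 1 - sse / sst,
         rmse = rmse,
         nrmse = rmse / rng,
         pbias = sum(err) / sum(measured) * 100,
         n = n),
    class = "cl_validation")
  rep$gfi_labels <- classify_gfi(rep)
  rep
}

#' @export
print.cl_validation <- function(x, digits = 4, ...) {
  cat(sprintf("Model validation (n = %d)\n", x$n))
  lab <- x$gfi_labels
  cat(sprintf("  r     = %8.4f  [%s]\n", x$r, lab[["r"]]))
  cat(sprintf("  R2    = %8.4f  [%s]\n", x$r2, lab[["r2"]]))
  cat(sprintf("  RMSE  = %8.4f mg/kg\n", x$rmse))
  cat(sprintf("  NRMSE = %8.4f  [%s]\n", x$nrmse, lab[["nrmse"]]))
  cat(sprintf("  PBIAS = %8.2f %%  [%s]\n", x$pbias, lab[["pbias"]]))
  invisible(x)
}

#' Goodness-of-fit rubric labels
#'
#' Classifies each validation metric into `"medium"`, `"high"` or
#' `"very_high"` bands:
#' \itemize{
#'   \item r: very high for `|r| > 0.8`; high for `0.6 < |r| <= 0.8`;
#'     medium otherwise.
#'   \item R2: very high for `>= 0.75`; high for `[0.65, 0.75)`; medium below.
#'   \item NRMSE: very high for `<= 0.5`; high for `(0.5, 0.7]`; medium above.
#'   \item PBIAS: very high within `[-25, 25]` %; high within `[-50, 50]`;
#'     medium beyond.
#' }
#' Where the published band endpoints overlap, the boundary value is assigned
#' to the better class.
#'
#' @param report a `cl_validation` object, or a named list/vector with
#'   elements `r`, `r2`, `nrmse`, `pbias`.
#' @return named character vector of labels for `r`, `r2`, `nrmse`, `pbias`.
#' @export
#' @examples
#' classify_gfi(list(r = 0.976, r2 = 0.927, nrmse = 0.054, pbias = 5))
classify_gfi <- function(report) {
  g <- function(nm) {
    v <- report[[nm]]
    if (is.null(v) || !is.finite(v)) stop("missing metric: ", nm, call. = FALSE)
    v
  }
  band_r <- function(r) {
    a <- abs(r)
    if (a > 0.8) "very_high" else if (a > 0.6) "high" else "medium"
  }
  band_r2 <- function(r2) {
    if (r2 >= 0.75) "very_high" else if (r2 >= 0.65) "high" else "medium"
  }
  band_nrmse <- function(x) {
    if (x <= 0.5) "very_high" else if (x <= 0.7) "high" else "medium"
  }
  band_pbias <- function(p) {
    a <- abs(p)
    if (a <= 25) "very_high" else if (a <= 50) "high" else "medium"
  }
  c(r = band_r(g("r")), r2 = band_r2(g("r2")),
    nrmse = band_nrmse(g("nrmse")), pbias = band_pbias(g("pbias")))
}

#' PBIAS interval across groups
#'
#' Published validation tables report PBIAS as an interval across sampling
#' groups (dates x treatments) rather than a single pooled number. This
#' helper computes PBIAS per group and returns the range.
#'
#' @param measured,modeled numeric vectors.
#' @param group a factor or vector defining the grouping.
#' @return named numeric vector `c(min, max)` of per-group PBIAS (%).
#' @export
pbias_interval <- function(measured, modeled, group) {
  stopifnot(length(measured) == length(modeled),
            length(group) == length(measured))
  per <- tapply(seq_along(measured), group, function(i)
    sum(measured[i] - modeled[i]) / sum(measured[i]) * 100)
  c(min = min(per), max = max(per))
}
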