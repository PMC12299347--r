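## Chloride stock accounting: concentrations to area-based stocks, leaching
## factor and residual ratio budgets, and fertilizer scheme arithmetic.

#' Area-based chloride stock of a soil layer
#'
#' Converts a water-soluble Cl- concentration to an area-based stock.
#' With concentration in mg/kg, bulk density in g/cm3 and layer depth in cm,
#' the soil mass under one hectare is `bulk_density * depth * 1e5` kg, so the
#' stock in kg/ha is `conc * bulk_density * depth * 0.1`.
#'
#' @param conc water-soluble Cl- concentration, mg/kg dry soil.
#' @param bulk_density soil bulk density, g/cm3.
#' @param depth layer thickness, cm (default 15, the standard sampling layer).
#' @return chloride stock in kg/ha; vectorised over `conc`.
#' @seealso [stock_to_conc()] for the exact inverse.
#' @export
#' @examples
#' cl_stock(20, 1.32, 15)   # 39.6 kg/ha
cl_stock <- function(conc, bulk_density, depth = 15) {
  check_nonneg(conc, "conc")
  check_nonneg(bulk_density, "bulk_density")
  check_nonneg(depth, "depth")
  conc * bulk_density * depth * 0.1
}

#' Concentration equivalent of an area-based chloride stock
#'
#' Exact inverse of [cl_stock()].
#'
#' @param stock chloride stock, kg/ha.
#' @inheritParams cl_stock
#' @return concentration in mg/kg.
#' @export
stock_to_conc <- function(stock, bulk_density, depth = 15) {
  check_nonneg(stock, "stock")
  check_nonneg(bulk_density, "bulk_density")
  if (any(bulk_density * depth == 0))
    stop("zero soil mass: bulk_density * depth must be positive", call. = FALSE)
  stock / (bulk_density * depth * 0.1)
}

#' Chloride leaching factor
#'
#' Fraction of the applied chloride dose no longer retained in the profiled
#' layers, relative to an unfertilized control:
#' `(cl_applied - (stock_treated - stock_control)) / cl_applied`.
#' When treated and control stocks are equal the whole dose has left the
#' profile and the factor is 1. Values outside `[0, 1]` (possible with
#' measurement noise) are returned unchanged and flagged `"out_of_range"`.
#'
#' @param cl_applied applied chloride, kg/ha; must be positive.
#' @param stock_treated Cl- stock of the treated profile, kg/ha.
#' @param stock_control Cl- stock of the control profile, kg/ha.
#' @return leaching factor as a fraction, possibly with a `"flag"` attribute.
#' @export
#' @examples
#' leaching_factor(37.5, 45, 40)   # 0.8667
leaching_factor <- function(cl_applied, stock_treated, stock_control) {
  check_finite(cl_applied, "cl_applied")
  if (any(cl_applied <= 0))
    stop("'cl_applied' must be positive", call. = FALSE)
  check_nonneg(stock_treated, "stock_treated")
  check_nonneg(stock_control, "stock_control")
  lf <- (cl_applied - (stock_treated - stock_control)) / cl_applied
  if (any(lf < 0 | lf > 1)) {
    warning("leaching factor outside [0, 1]; kept unclamped and flagged",
            call. = FALSE)
    lf <- flag_value(lf, "out_of_range")
  }
  lf
}

#' Chloride residual ratio
#'
#' Fraction of applied chloride remaining in the profile after subtracting
#' leaching and plant uptake: `1 - leaching_factor - plant_uptake`.
#'
#' @param leaching_factor fraction in `[0, 1]`.
#' @param plant_uptake plant Cl absorption fraction in `[0, 1]`.
#' @return residual ratio; negative results (inputs summing above 1) are
#'   retained and flagged `"negative_residual"`.
#' @export
residual_ratio <- function(leaching_factor, plant_uptake) {
  check_finite(leaching_factor, "leaching_factor")
  check_finite(plant_uptake, "plant_uptake")
  if (any(leaching_factor < 0 | leaching_factor > 1))
    stop("'leaching_factor' must be in [0, 1]", call. = FALSE)
  if (any(plant_uptake < 0 | plant_uptake > 1))
    stop("'plant_uptake' must be in [0, 1]", call. = FALSE)
  rr <- 1 - leaching_factor - plant_uptake
  if (any(rr < 0)) {
    warning("leaching + uptake exceed 1; negative residual ratio flagged",
            call. = FALSE)
    rr <- flag_value(rr, "negative_residual")
  }
  rr
}

#' Chloride budget for one treatment at one sampling date
#'
#' Combines the applied dose, treated and control profile stocks and an
#' assumed plant uptake fraction into a closed budget. By construction
#' `leaching_factor + residual_ratio + plant_uptake == 1`.
#'
#' @inheritParams leaching_factor
#' @param plant_uptake plant Cl absorption fraction (default 0.05). How this
#'   fraction is measured is outside the scope of the package; it is an input.
#' @param cum_rain optional cumulative rainfall (mm) at the sampling date,
#'   carried through for efficiency analysis.
#' @return an object of class `cl_budget`: a list with elements `cl_applied`,
#'   `stock_treated`, `stock_control`, `leaching_factor`, `plant_uptake`,
#'   `residual_ratio`, `cum_rain`.
#' @export
#' @examples
#' b <- cl_budget(75, 105, 75, plant_uptake = 0.05)
#' b$leaching_factor   # 0.6
cl_budget <- function(cl_applied, stock_treated, stock_control,
                      plant_uptake = 0.05, cum_rain = NA_real_) {
  lf <- suppressWarnings(
    leaching_factor(cl_applied, stock_treated, stock_control))
  rr <- 1 - as.numeric(lf) - plant_uptake
  out <- structure(
    list(cl_applied = cl_applied,
         stock_treated = stock_treated,
         stock_control = stock_control,
         leaching_factor = as.numeric(lf),
         plant_uptake = plant_uptake,
         residual_ratio = rr,
         cum_rain = cum_rain),
    class = "cl_budget")
  fl <- flags(lf)
  if (!is.null(fl)) attr(out, "flag") <- fl
  if (rr < 0) attr(out, "flag") <- c(attr(out, "flag"), "negative_residual")
  out
}

#' @export
print.cl_budget <- function(x, digits = 4, ...) {
  cat("Chloride budget\n")
  cat(sprintf("  applied dose:      %8.2f kg/ha\n", x$cl_applied))
  cat(sprintf("  treated stock:     %8.2f kg/ha\n", x$stock_treated))
  cat(sprintf("  control stock:     %8.2f kg/ha\n", x$stock_control))
  cat(sprintf("  leaching factor:   %8.1f %%\n", 100 * x$leaching_factor))
  cat(sprintf("  plant uptake:      %8.1f %%\n", 100 * x$plant_uptake))
  cat(sprintf("  residual ratio:    %8.1f %%\n", 100 * x$residual_ratio))
  if (!is.null(flags(x))) cat("  flags:", paste(flags(x), collapse = ", "), "\n")
  invisible(x)
}

#' Fertilizer scheme for a chloride treatment
#'
#' Computes the KCl mass delivering a target chloride rate and the K2SO4
#' complement keeping the basal K2O supply constant across treatments.
#' KCl is taken as 60 % K2O and 45 % Cl by mass; the basal K2O target is
#' 150 kg/ha by default. Reported KCl masses are rounded to whole kg;
#' full precision is kept in the `_exact` fields.
#'
#' @param cl_rate target chloride application, kg Cl/ha.
#' @param basal_k2o_target basal K2O supply to hold constant, kg/ha.
#' @param kcl_cl_fraction mass fraction of Cl in KCl fertilizer (default 0.45).
#' @param kcl_k2o_fraction mass fraction of K2O in KCl fertilizer (default 0.60).
#' @param n_rate,p2o5_rate nitrogen and phosphate rates carried for reporting.
#' @return an object of class `fertilizer_scheme` with elements `cl_rate`,
#'   `kcl_mass` (rounded), `kcl_mass_exact`, `kcl_k2o`, `k2so4_k2o`,
#'   `n_rate`, `p2o5_rate` and the grade fractions.
#' @export
#' @examples
#' build_scheme(37.5)    # 83 kg KCl/ha, K2O split 50 + 100
build_scheme <- function(cl_rate, basal_k2o_target = 150,
                         kcl_cl_fraction = 0.45, kcl_k2o_fraction = 0.60,
                         n_rate = 100, p2o5_rate = 90) {
  check_nonneg(cl_rate, "cl_rate")
  check_nonneg(basal_k2o_target, "basal_k2o_target")
  if (kcl_cl_fraction <= 0 || kcl_cl_fraction > 1 ||
      kcl_k2o_fraction <= 0 || kcl_k2o_fraction > 1)
    stop("fertilizer grade fractions must lie in (0, 1]", call. = FALSE)
  kcl_mass <- cl_rate / kcl_cl_fraction
  kcl_k2o <- kcl_mass * kcl_k2o_fraction
  if (kcl_k2o > basal_k2o_target + 1e-9) {
    max_cl <- basal_k2o_target / kcl_k2o_fraction * kcl_cl_fraction
    stop(sprintf(
      "KCl-derived K2O (%.1f) exceeds the basal target (%.1f); maximum feasible cl_rate is %.2f kg/ha",
      kcl_k2o, basal_k2o_target, max_cl), call. = FALSE)
  }
  structure(
    list(cl_rate = cl_rate,
         kcl_mass = round(kcl_mass),
         kcl_mass_exact = kcl_mass,
         kcl_k2o = kcl_k2o,
         k2so4_k2o = basal_k2o_target - kcl_k2o,
         basal_k2o_target = basal_k2o_target,
         n_rate = n_rate,
         p2o5_rate = p2o5_rate,
         kcl_cl_fraction = kcl_cl_fraction,
         kcl_k2o_fraction = kcl_k2o_fraction),
    class = "fertilizer_scheme")
}

#' @export
print.fertilizer_scheme <- function(x, ...) {
  cat("Fertilizer scheme (basal application)\n")
  cat(sprintf("  Cl rate:        %6.1f kg/ha\n", x$cl_rate))
  cat(sprintf("  KCl mass:       %6d kg/ha (exact %.2f)\n",
              x$kcl_mass, x$kcl_mass_exact))
  cat(sprintf("  K2O from KCl:   %6.1f kg/ha\n", x$kcl_k2o))
  cat(sprintf("  K2O from K2SO4: %6.1f kg/ha\n", x$k2so4_k2o))
  cat(sprintf("  N / P2O5:       %6.1f / %.1f kg/ha\n", x$n_rate, x$p2o5_rate))
  invisible(x)
}

#' Field plot area from the ridge layout
#'
#' Trial plots consist of parallel ridges; the plot area is simply
#' `n_ridges * ridge_length * ridge_width`.
#'
#' @param n_ridges number of ridges per plot (default 6).
#' @param ridge_length_m ridge length, m (default 12).
#' @param ridge_width_m ridge width, m (default 0.8).
#' @return plot area in m2.
#' @export
#' @examples
#' plot_area()   # 57.6 m2
plot_area <- function(n_ridges = 6, ridge_length_m = 12, ridge_width_m = 0.8) {
  check_nonneg(n_ridges, "n_ridges")
  check_nonneg(ridge_length_m, "ridge_length_m")
  check_nonneg(ridge_width_m, "ridge_width_m")
  n_ridges * ridge_length_m * ridge_width_m
}
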