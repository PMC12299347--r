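## Observation-table I/O, budget computation over a trial, and the
## end-to-end pipeline driver.

obs_required_cols <- c("site_id", "texture", "treatment", "das",
                       "cum_rain_mm", "layer_top_cm", "layer_bottom_cm",
                       "cl_mgkg", "replicate")

#' Read a long-format observation table
#'
#' Reads and validates the CSV schema used throughout the package: one row
#' per site/treatment/replicate/date/layer with the water-soluble Cl-
#' concentration and an optional SO4^2- column. Errors name the offending
#' row and column.
#'
#' @param path path to a CSV file (UTF-8, header required).
#' @return a validated data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(df)
}

#' Validate an observation table
#'
#' @param df a data frame with the observation-table columns.
#' @return the data frame, invisibly validated (numeric columns coerced).
#' @export
validate_observations <- function(df) {
  miss <- setdiff(obs_required_cols, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  num_cols <- c("das", "cum_rain_mm", "layer_top_cm", "layer_bottom_cm",
                "cl_mgkg", "replicate")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d", cl, bad[1]),
           call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing value in column '%s', row %d", cl, which(is.na(v))[1]),
           call. = FALSE)
    df[[cl]] <- v
  }
  neg <- which(df$cl_mgkg < 0)
  if (length(neg))
    stop(sprintf("negative concentration in column 'cl_mgkg', row %d", neg[1]),
         call. = FALSE)
  bad_layer <- which(df$layer_bottom_cm <= df$layer_top_cm)
  if (length(bad_layer))
    stop(sprintf("layer_bottom_cm <= layer_top_cm in row %d", bad_layer[1]),
         call. = FALSE)
  df
}

#' Write an observation table
#'
#' Plain CSV with header, full precision (round trips are lossless well
#' below 1e-12 relative).
#'
#' @param df observation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chloride budgets per treatment and sampling date
#'
#' Sums per-layer stocks over the 0-45 cm profile (averaging replicates),
#' subtracts the control profile at the matched date, and closes the budget
#' with the assumed plant-uptake fraction.
#'
#' @param obs an observation table (see [read_observations()]).
#' @param bulk_density soil bulk density, g/cm3.
#' @param dose_map named vector mapping treatment labels to applied doses in
#'   kg Cl/ha; the 0 entry is the control.
#' @param plant_uptake plant Cl absorption fraction.
#' @return a data frame with one row per treated treatment x date:
#'   `treatment`, `cum_rain`, `cl_applied`, `stock_treated`, `stock_control`,
#'   `leaching_factor`, `residual_ratio`.
#' @export
compute_budgets <- function(obs, bulk_density,
                            dose_map = c(CK = 0, L = 37.5, M = 75, H = 112.5),
                            plant_uptake = 0.05) {
  obs <- validate_observations(obs)
  unknown <- setdiff(unique(obs$treatment), names(dose_map))
  if (length(unknown))
    stop("treatment(s) not in dose_map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ctrl_lab <- names(dose_map)[dose_map == 0]
  if (!length(ctrl_lab)) stop("dose_map needs a zero-dose control", call. = FALSE)
  depth_stock <- function(sub) {
    # replicate-mean concentration per layer, summed over layers
    per_layer <- tapply(sub$cl_mgkg, sub$layer_top_cm, mean)
    sum(cl_stock(per_layer, bulk_density, 15))
  }
  dates <- sort(unique(obs$cum_rain_mm))
  treated <- setdiff(names(dose_map)[dose_map > 0], character(0))
  treated <- intersect(treated, unique(obs$treatment))
  rows <- list()
  for (tr in treated) {
    for (d in dates) {
      sub_t <- obs[obs$treatment == tr & obs$cum_rain_mm == d, ]
      sub_c <- obs[obs$treatment %in% ctrl_lab & obs$cum_rain_mm == d, ]
      if (!nrow(sub_t) || !nrow(sub_c)) next
      st <- depth_stock(sub_t)
      sc <- depth_stock(sub_c)
      lf <- suppressWarnings(leaching_factor(dose_map[[tr]], st, sc))
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, cum_rain = d, cl_applied = dose_map[[tr]],
        stock_treated = st, stock_control = sc,
        leaching_factor = as.numeric(lf),
        residual_ratio = 1 - as.numeric(lf) - plant_uptake,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no treated observations found", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Cheap deterministic checksum of a configuration (djb2 over its deparse),
## recorded in run logs so artifacts can be traced to their settings.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a synthetic trial
#'
#' Composes the stages end to end: simulate (or accept) a trial, compute
#' chloride budgets and efficiency series, solve critical rainfall, fit
#' per-treatment/layer rainfall-response quadratics, validate the residual
#' estimation model against the trial's profile-mean contents, and solve the
#' safe KCl range from the yields. Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @param trial optionally a pre-built [simulate_trial()] result; simulated
#'   from `config` when omitted.
#' @param model the residual estimation model to validate (default the
#'   published coefficients).
#' @param out_dir optional directory; when given, writes `observations.csv`,
#'   `budgets.csv`, `quad_fits.csv`, `validation.json`, `safe_range.json`
#'   and `run_log.txt`.
#' @return an object of class `cl_pipeline`: list with `budgets`,
#'   `efficiency` (per treatment), `critical_rain_30`, `quad_fits`,
#'   `validation`, `safe_range`, `trial`, `log`.
#' @export
run_pipeline <- function(config = generator_config(), trial = NULL,
                         model = cl_residual_model(), out_dir = NULL) {
  if (is.null(trial)) trial <- simulate_trial(config)
  obs <- trial$observations
  doses <- config$cl_doses
  dose_map <- stats::setNames(doses, treatment_labels(doses))
  budgets <- compute_budgets(obs, config$bulk_density, dose_map,
                             config$plant_uptake)

  eff <- split(budgets[, c("cum_rain", "leaching_factor")], budgets$treatment)
  eff <- lapply(eff, function(d)
    data.frame(cum_rain = d$cum_rain, efficiency = d$leaching_factor,
               out_of_range = d$leaching_factor < 0 | d$leaching_factor > 1))
  crit30 <- vapply(eff, function(p)
    as.numeric(tryCatch(critical_rainfall(p, 0.30), error = function(e) NA_real_)),
    numeric(1))

  # rainfall-response quadratics per treated treatment x layer
  treated <- names(dose_map)[dose_map > 0]
  qf <- list()
  for (tr in treated) for (top in c(0, 15, 30)) {
    sub <- obs[obs$treatment == tr & obs$layer_top_cm == top, ]
    agg <- stats::aggregate(cl_mgkg ~ cum_rain_mm, data = sub, FUN = mean)
    if (length(unique(agg$cum_rain_mm)) < 4) next
    f <- fit_quadratic_response(agg$cum_rain_mm, agg$cl_mgkg)
    qf[[length(qf) + 1L]] <- data.frame(
      treatment = tr, layer_top = top, layer_bottom = top + 15,
      a = f$a, b = f$b, c = f$c, pearson_r = f$pearson_r,
      stringsAsFactors = FALSE)
  }
  quad_fits <- do.call(rbind, qf)

  # validate the residual model on profile-aggregate contents (sum of the
  # three replicate-mean layer concentrations, the scale of the model's Y)
  prof <- stats::aggregate(cl_mgkg ~ treatment + cum_rain_mm, data = obs,
                           FUN = mean)
  prof$cl_profile <- prof$cl_mgkg * 3   # mean over layers -> sum over layers
  prof <- prof[prof$treatment %in% treated, ]
  prof$dose <- dose_map[prof$treatment]
  prof$pred <- as.numeric(predict(model, prof$cum_rain_mm, prof$dose,
                                  config$clay, clamp = TRUE))
  validation <- compute_metrics(prof$cl_profile, prof$pred)

  yields <- trial$yields
  ck <- mean(yields$yield_t_ha[yields$dose == 0])
  agg_y <- stats::aggregate(yield_t_ha ~ dose, data = yields, FUN = mean)
  ry <- relative_yield(agg_y$yield_t_ha, ck)
  dr <- tryCatch(fit_dose_response(agg_y$dose, ry), warning = function(w) NULL,
                 error = function(e) NULL)
  safe <- if (!is.null(dr) && is.finite(dr$p2) && dr$p2 < 0)
    tryCatch(safe_dose_range(dr), error = function(e) NULL) else NULL

  log <- c(sprintf("clleach %s", as.character(utils::packageVersion("clleach"))),
           sprintf("seed: %d", config$seed),
           sprintf("config hash: %s", config_hash(unclass(config))),
           sprintf("observations: %d rows", nrow(obs)))
  out <- structure(
    list(budgets = budgets, efficiency = eff, critical_rain_30 = crit30,
         quad_fits = quad_fits, validation = validation,
         dose_response = dr, safe_range = safe, trial = trial, log = log),
    class = "cl_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_observations(obs, file.path(out_dir, "observations.csv"))
    utils::write.csv(budgets, file.path(out_dir, "budgets.csv"), row.names = FALSE)
    if (!is.null(quad_fits))
      utils::write.csv(quad_fits, file.path(out_dir, "quad_fits.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(r = validation$r, r2 = validation$r2, rmse = validation$rmse,
           nrmse = validation$nrmse, pbias = validation$pbias,
           gfi = as.list(validation$gfi_labels)),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(safe))
      jsonlite::write_json(
        list(dose_ry100 = safe$dose_ry100, dose_ry95 = safe$dose_ry95,
             kcl_ry100 = safe$kcl_ry100, kcl_ry95 = safe$kcl_ry95),
        file.path(out_dir, "safe_range.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.cl_pipeline <- function(x, ...) {
  cat("Chloride leaching pipeline result\n")
  cat(sprintf("  budgets: %d treatment x date rows\n", nrow(x$budgets)))
  cat("  critical rainfall at 30 % efficiency (mm):\n")
  print(round(x$critical_rain_30, 1))
  cat(sprintf("  residual-model validation: R2 = %.3f, NRMSE = %.3f\n",
              x$validation$r2, x$validation$nrmse))
  if (!is.null(x$safe_range))
    cat(sprintf("  safe KCl range: %.0f-%.0f kg/ha\n",
                x$safe_range$kcl_ry100, x$safe_range$kcl_ry95))
  invisible(x)
}
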