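## Orchestration of the two study arms over TG files, with CSV + JSON
## reports. The nonisothermal arm runs window selection -> conversion ->
## isoconversional profile; the isothermal arm runs per-temperature model
## combination -> per-model Arrhenius fits -> shelf-life table, with an
## optional cross-check against a nonisothermal Ea profile.

#' Study configuration
#'
#' Validates and freezes the settings of a study run; the resolved
#' configuration is written alongside every report so runs are auditable.
#'
#' @param files character vector of TG file paths (may be empty when curves
#'   are passed directly to the run functions).
#' @param window_C step temperature window for nonisothermal inputs, degC.
#' @param alpha_grid conversion grid for the isoconversional profile.
#' @param codes kinetic model subset.
#' @param Ea_bounds isoconversional search interval, J/mol.
#' @param clip_eps conversion clip for divergent transforms.
#' @param query_T_C shelf-life query temperatures, degC.
#' @param iso_mf known step plateau mass in mg for isothermal runs that end
#'   before the step completes (see [compute_conversion()]); `NULL` uses the
#'   record's final mass.
#' @param out_dir report directory (created on demand).
#' @param seed integer seed recorded with the run (generators are the only
#'   consumers of randomness).
#' @return a `study_config` list.
#' @export
study_config <- function(files = character(),
                         window_C = c(134, 279),
                         alpha_grid = seq(0.10, 0.90, by = 0.10),
                         codes = TEN_MODEL_SET,
                         Ea_bounds = c(10e3, 400e3),
                         clip_eps = 1e-6,
                         query_T_C = c(158, 25),
                         iso_mf = NULL,
                         out_dir = NULL,
                         seed = 1L) {
  stopifnot(is.character(files),
            length(window_C) == 2L, window_C[1] < window_C[2],
            all(alpha_grid > 0 & alpha_grid < 1),
            !is.unsorted(alpha_grid, strictly = TRUE),
            length(Ea_bounds) == 2L, Ea_bounds[1] > 0,
            Ea_bounds[1] < Ea_bounds[2],
            clip_eps > 0, clip_eps < 0.5,
            length(query_T_C) >= 1L)
  kinetic_models(codes)  # validates the subset
  structure(list(files = files, window_C = window_C, alpha_grid = alpha_grid,
                 codes = codes, Ea_bounds = Ea_bounds, clip_eps = clip_eps,
                 query_T_C = query_T_C, iso_mf = iso_mf, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "study_config")
}

.write_report <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.write_config <- function(config, path, extra = list()) {
  snap <- c(unclass(config), extra)
  snap$out_dir <- NULL
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the nonisothermal study arm
#'
#' Reads the configured TG files (or takes prebuilt runs/curves), isolates
#' the step window, computes conversion, and estimates the Ea(alpha) profile
#' by the nonlinear Vyazovkin method. When `config$out_dir` is set, writes
#' `vyazovkin_profile.csv` (alpha, Ea_kJ_mol, objective, dispersion),
#' `vyazovkin_dispersion.csv` (the per-level dispersion table), and
#' `nonisothermal_config.json`.
#'
#' @param config a `study_config`.
#' @param runs optional list of `nonisothermal_run`s or nonisothermal
#'   `conversion_curve`s, bypassing file input.
#' @return an `isoconversional_result`, invisibly when reports are written.
#' @export
run_nonisothermal_study <- function(config, runs = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(runs)) {
    runs <- .stage("read", lapply(config$files, read_tg_table,
                                  kind = "nonisothermal"))
  }
  if (length(runs) < 2L) stop("[validate] need >= 2 nonisothermal inputs")
  curves <- .stage("conversion", lapply(runs, function(r) {
    if (inherits(r, "conversion_curve")) r
    else compute_conversion(r, window = select_step_window(r, config$window_C))
  }))
  prof <- .stage("isoconversional",
                 isoconversional_profile(curves, alpha_grid = config$alpha_grid,
                                         bounds = config$Ea_bounds))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_report(prof$points, file.path(config$out_dir, "vyazovkin_profile.csv"))
    .write_report(prof$points[, c("alpha", "dispersion")],
                  file.path(config$out_dir, "vyazovkin_dispersion.csv"))
    .write_config(config, file.path(config$out_dir, "nonisothermal_config.json"),
                  extra = list(heating_rates = prof$heating_rates))
    return(invisible(prof))
  }
  prof
}

#' Run the isothermal study arm
#'
#' For each isothermal input: model-combination report (per-model k, k0,
#' residual, output weight, contribution). Across temperatures: per-model
#' Arrhenius fits and the shelf-life table at the query temperatures. When a
#' nonisothermal `isoconversional_result` is supplied, the mean isothermal
#' Ea (over models with positive rate constants at every temperature) is
#' compared with the mean Ea(alpha) of the profile — the standard
#' cross-protocol consistency check.
#'
#' When `config$out_dir` is set, writes one `combination_<T>C.csv` per
#' temperature, `shelf_life_table.csv`, `isothermal_summary.json`, and
#' `isothermal_config.json`.
#'
#' @param config a `study_config`.
#' @param runs optional list of `isothermal_run`s or isothermal
#'   `conversion_curve`s, bypassing file input.
#' @param noniso_profile optional `isoconversional_result` for the
#'   cross-arm Ea comparison.
#' @return list with `combinations`, `shelf_life`, and `summary`.
#' @export
run_isothermal_study <- function(config, runs = NULL, noniso_profile = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(runs)) {
    runs <- .stage("read", lapply(config$files, read_tg_table,
                                  kind = "isothermal"))
  }
  if (length(runs) < 2L) stop("[validate] need >= 2 isothermal inputs")
  curves <- .stage("conversion", lapply(runs, function(r) {
    if (inherits(r, "conversion_curve")) r
    else compute_conversion(r, mf = config$iso_mf)
  }))
  temps <- vapply(curves, `[[`, numeric(1), "temperature_K")
  if (anyDuplicated(temps)) stop("[validate] isothermal temperatures must be distinct")
  combos <- .stage("combination", lapply(curves, combination_report,
                                         codes = config$codes,
                                         clip_eps = config$clip_eps))
  slt <- .stage("shelf_life", shelf_life_table(combos, query_T_C = config$query_T_C))
  ## the headline isothermal Ea is the dominant model's: misfit models carry
  ## arbitrary Arrhenius slopes, so a plain mean over the ensemble would be
  ## meaningless; the dominant model (largest mean contribution across
  ## temperatures) is how the isothermal analysis selects its mechanism
  contrib <- vapply(combos, `[[`, numeric(length(config$codes)),
                    "contributions")
  if (is.null(dim(contrib))) {  # single-model subset
    contrib <- matrix(contrib, nrow = 1,
                      dimnames = list(names(combos[[1]]$contributions), NULL))
  }
  mean_contrib <- rowMeans(contrib)
  best_model <- names(which.max(mean_contrib))
  best_Ea <- slt$Ea_kJ_mol[slt$model == best_model]
  summary <- list(
    temperatures_C = kelvin_to_celsius(temps),
    residual_errors = vapply(combos, `[[`, numeric(1), "residual_error"),
    mean_isothermal_Ea_kJ_mol = mean(slt$Ea_kJ_mol, na.rm = TRUE),
    dominant_model = best_model,
    dominant_model_Ea_kJ_mol = best_Ea
  )
  if (!is.null(noniso_profile)) {
    mean_noniso <- mean(noniso_profile$points$Ea_kJ_mol)
    summary$mean_nonisothermal_Ea_kJ_mol <- mean_noniso
    summary$cross_arm_rel_diff <- abs(best_Ea - mean_noniso) /
      mean(c(best_Ea, mean_noniso))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(combos)) {
      .write_report(as.data.frame(combos[[i]]),
                    file.path(config$out_dir,
                              sprintf("combination_%gC.csv",
                                      kelvin_to_celsius(temps[i]))))
    }
    .write_report(slt, file.path(config$out_dir, "shelf_life_table.csv"))
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "isothermal_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_config(config, file.path(config$out_dir, "isothermal_config.json"))
  }
  list(combinations = combos, shelf_life = slt, summary = summary)
}
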