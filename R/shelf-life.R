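## Arrhenius extrapolation of isothermal rate constants and t90 shelf life.
##
## Per-model rate constants fitted at the accelerated isothermal
## temperatures are regressed as ln k against 1/T (slope -Ea/R, intercept
## lnA) and extrapolated to storage temperature; the t90 shelf life is the
## time to 10 percent conversion, t90 = g(0.10) / k(T).

#' Arrhenius fit of rate constants across temperatures
#'
#' @param code model code the rate constants belong to.
#' @param T_K temperatures in kelvin (>= 2 distinct values).
#' @param k rate constants in 1/min (> 0), same length as `T_K`.
#' @return an `arrhenius_fit`: `code`, `Ea` (J/mol), `lnA` (A in 1/min),
#'   `n_temperatures`, `r_squared`, `residuals` (of ln k on 1/T).
#' @export
arrhenius_fit <- function(code, T_K, k) {
  stopifnot(length(T_K) == length(k))
  if (length(unique(T_K)) < 2L) stop("Arrhenius fit needs >= 2 distinct temperatures")
  if (any(k <= 0)) stop("rate constants must be positive for model ", code)
  x <- 1 / T_K
  y <- log(k)
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[[2]]
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(code = code, Ea = -slope * R_GAS, lnA = stats::coef(fit)[[1]],
         n_temperatures = length(T_K),
         r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
         residuals = res),
    class = "arrhenius_fit")
}

#' Rate constant at a query temperature from an Arrhenius fit
#'
#' @param fit an `arrhenius_fit`.
#' @param T_K temperature(s) in kelvin.
#' @return k(T) in 1/min.
#' @export
rate_constant_at <- function(fit, T_K) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  if (any(T_K <= 0)) stop("temperature must be positive (kelvin)")
  exp(fit$lnA - fit$Ea / (R_GAS * T_K))
}

#' t90 shelf life at a query temperature
#'
#' Time for 10 percent conversion under the given kinetic model:
#' `t90 = g(0.10) / k(T)` minutes. The fitted intercept k0 of the
#' linearised isothermal fit is deliberately excluded: it absorbs
#' experimental offsets (heat-up, baseline) that should not extrapolate to
#' storage conditions.
#'
#' For a model whose g(0.10) is not positive (the autocatalytic Au form,
#' whose integral form is negative below half conversion), a t90 measured
#' from the start of the reaction is ill-defined; `NA` is returned with a
#' warning.
#'
#' @param model `kinetic_model` or code.
#' @param fit an `arrhenius_fit` for that model.
#' @param T_K query temperature in kelvin.
#' @return a `shelf_life_entry`: `code`, `temperature_K`, `k_at_T` (1/min),
#'   `t90_min`, `t90_h`, `t90_years`.
#' @export
t90_shelf_life <- function(model, fit, T_K) {
  if (is.character(model)) model <- kinetic_model(model)
  k <- rate_constant_at(fit, T_K)
  g10 <- model$g(0.10)
  if (g10 <= 0) {
    warning("g(0.10) <= 0 for model ", model$code,
            "; t90 from reaction start is ill-defined, returning NA")
    t90 <- NA_real_
  } else {
    t90 <- g10 / k
  }
  structure(
    list(code = model$code, temperature_K = T_K, k_at_T = k,
         t90_min = t90, t90_h = t90 / 60, t90_years = t90 / MIN_PER_YEAR),
    class = "shelf_life_entry")
}

#' Shelf-life table across models and query temperatures
#'
#' Collects each model's fitted rate constants from per-temperature
#' combination results, fits the Arrhenius law per model, and tabulates Ea,
#' lnA and t90 at the query temperatures (by convention the first is
#' reported in hours — the accelerated condition — and any 25 degC entry
#' also in years). Models whose fitted rate constant is non-positive at any
#' temperature cannot be extrapolated and are returned with NA entries.
#'
#' @param combos list of `combination_result`s, one per isothermal
#'   temperature (>= 2 distinct temperatures).
#' @param query_T_C query temperatures in degrees Celsius.
#' @return data.frame with one row per model: `model`, `Ea_kJ_mol`, `ln_A`,
#'   then for each query temperature `k_<T>C_min` (1/min), `t90_<T>C_h` and
#'   `t90_<T>C_years`.
#' @export
shelf_life_table <- function(combos, query_T_C = c(158, 25)) {
  stopifnot(length(combos) >= 2L)
  temps <- vapply(combos, `[[`, numeric(1), "temperature_K")
  if (length(unique(temps)) < 2L) stop("need >= 2 distinct isothermal temperatures")
  codes <- names(combos[[1]]$w2)
  rows <- lapply(codes, function(code) {
    k <- vapply(combos, function(co) co$fits[[code]]$k, numeric(1))
    base <- data.frame(model = code, Ea_kJ_mol = NA_real_, ln_A = NA_real_)
    if (any(k <= 0)) {
      fit <- NULL
    } else {
      fit <- arrhenius_fit(code, temps, k)
      base$Ea_kJ_mol <- fit$Ea / 1e3
      base$ln_A <- fit$lnA
    }
    for (Tq in query_T_C) {
      cols <- paste0(c("k_", "t90_", "t90_"), Tq, c("C_min", "C_h", "C_years"))
      if (is.null(fit)) {
        base[cols] <- NA_real_
      } else {
        ## NA t90 for models without a positive g(0.10) is expected (Au);
        ## the per-entry warning is redundant inside the table
        entry <- suppressWarnings(t90_shelf_life(code, fit, celsius_to_kelvin(Tq)))
        base[cols] <- c(entry$k_at_T, entry$t90_h, entry$t90_years)
      }
    }
    base
  })
  do.call(rbind, rows)
}
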