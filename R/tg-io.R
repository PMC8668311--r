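## Reading/writing TG traces and converting mass loss to conversion degree.
##
## Temperatures are stored in kelvin internally; all file and argument I/O is
## in degrees Celsius. Time is in minutes throughout.

#' Construct an isothermal TG run
#'
#' @param temperature_C hold temperature in degrees Celsius (scalar).
#' @param time_min sampling times in minutes, strictly increasing from 0.
#' @param mass_mg sample mass in mg, same length as `time_min`.
#' @param label free-text label.
#' @return an `isothermal_run` object (temperature stored in kelvin).
#' @export
isothermal_run <- function(temperature_C, time_min, mass_mg, label = "") {
  stopifnot(length(temperature_C) == 1L)
  if (!is.na(temperature_C)) stopifnot(is.finite(temperature_C))
  if (length(time_min) < 5L) stop("an isothermal run needs at least 5 points")
  if (length(mass_mg) != length(time_min)) stop("time and mass lengths differ")
  d <- diff(time_min)
  if (any(d <= 0)) {
    stop("time must be strictly increasing; first offending row: ",
         which(d <= 0)[1] + 1L)
  }
  if (time_min[1] < 0) stop("time must start at or after 0")
  if (any(!is.finite(mass_mg))) stop("mass contains non-finite values")
  structure(
    list(temperature_K = celsius_to_kelvin(temperature_C),
         time_min = as.numeric(time_min), mass_mg = as.numeric(mass_mg),
         label = label),
    class = "isothermal_run")
}

#' Construct a nonisothermal (constant heating rate) TG run
#'
#' @param heating_rate heating rate beta in degrees Celsius per minute.
#' @param temperature_C temperature series in degrees Celsius, strictly
#'   increasing.
#' @param mass_mg sample mass in mg.
#' @param label free-text label.
#' @param time_min optional time column; if present its implied heating rate
#'   must agree with `heating_rate` within 1 percent.
#' @return a `nonisothermal_run` object (temperatures stored in kelvin).
#' @export
nonisothermal_run <- function(heating_rate, temperature_C, mass_mg,
                              label = "", time_min = NULL) {
  stopifnot(length(heating_rate) == 1L, heating_rate > 0)
  if (length(temperature_C) < 5L) stop("a nonisothermal run needs at least 5 points")
  if (length(mass_mg) != length(temperature_C)) stop("temperature and mass lengths differ")
  d <- diff(temperature_C)
  if (any(d <= 0)) {
    stop("temperature must be strictly increasing; first offending row: ",
         which(d <= 0)[1] + 1L)
  }
  if (any(!is.finite(mass_mg))) stop("mass contains non-finite values")
  if (!is.null(time_min)) {
    implied <- stats::coef(stats::lm(temperature_C ~ time_min))[[2]]
    if (abs(implied - heating_rate) > 0.01 * heating_rate) {
      stop(sprintf("time column implies a heating rate of %.4g, inconsistent with beta = %.4g",
                   implied, heating_rate))
    }
  }
  structure(
    list(heating_rate = heating_rate,
         temperature_K = celsius_to_kelvin(as.numeric(temperature_C)),
         mass_mg = as.numeric(mass_mg), label = label,
         time_min = if (is.null(time_min)) NULL else as.numeric(time_min)),
    class = "nonisothermal_run")
}

#' Construct a conversion curve
#'
#' A conversion curve holds the degree of conversion alpha of one
#' decomposition step against time (isothermal) or temperature in kelvin
#' (nonisothermal), together with the mass baseline (m0, mf) and window used
#' to compute it.
#'
#' @param abscissa time in minutes (isothermal) or temperature in kelvin
#'   (nonisothermal), strictly increasing.
#' @param alpha conversion series in `[0, 1]`.
#' @param source_kind `"isothermal"` or `"nonisothermal"`.
#' @param m0,mf initial/final step mass in mg (may be `NA` for synthetic
#'   curves generated directly in conversion units).
#' @param window abscissa interval the step was isolated on.
#' @param temperature_K hold temperature (isothermal curves).
#' @param heating_rate heating rate in degrees Celsius/min (nonisothermal curves).
#' @param partial flag set when the curve does not traverse (0.01, 0.99)
#'   inside the window.
#' @param monotone_tol tolerated local decrease in alpha before a quality
#'   warning is raised; noisy curves may pass a larger value.
#' @return a `conversion_curve` object.
#' @export
conversion_curve <- function(abscissa, alpha,
                             source_kind = c("isothermal", "nonisothermal"),
                             m0 = NA_real_, mf = NA_real_, window = range(abscissa),
                             temperature_K = NA_real_, heating_rate = NA_real_,
                             partial = NA, monotone_tol = 1e-3) {
  source_kind <- match.arg(source_kind)
  stopifnot(length(abscissa) == length(alpha))
  if (any(diff(abscissa) <= 0)) stop("abscissa must be strictly increasing")
  if (any(alpha < -1e-12 | alpha > 1 + 1e-12)) stop("alpha outside [0, 1]")
  drops <- diff(alpha)
  if (any(drops < -monotone_tol)) {
    warning(sprintf("alpha decreases by more than %g within the curve (noisy or multi-step data?)",
                    monotone_tol))
  }
  if (is.na(partial)) {
    partial <- !(alpha[1] <= 0.01 && alpha[length(alpha)] >= 0.99)
  }
  structure(
    list(abscissa = as.numeric(abscissa), alpha = pmin(pmax(alpha, 0), 1),
         source_kind = source_kind, m0 = m0, mf = mf, window = window,
         temperature_K = temperature_K, heating_rate = heating_rate,
         partial = partial),
    class = "conversion_curve")
}

#' @export
print.conversion_curve <- function(x, ...) {
  cat(sprintf("<conversion_curve %s, %d points, alpha %.3f..%.3f%s>\n",
              x$source_kind, length(x$alpha), min(x$alpha), max(x$alpha),
              if (isTRUE(x$partial)) ", partial" else ""))
  invisible(x)
}

.REQUIRED_COLS <- c(isothermal = "time_min", nonisothermal = "temp_C")

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
}

#' Read a TG trace from delimited text
#'
#' Reads a CSV/TSV file with headered columns among `time_min`, `temp_C`,
#' `mass_mg` (nonstandard headers can be mapped via `dialect`). The run kind
#' is autodetected: a file whose temperature column is constant to within
#' 1 degree C (or absent) is isothermal; a file with a rising temperature
#' ramp is nonisothermal.
#'
#' Isothermal files that include the initial heat-up ramp are trimmed to the
#' first sample within `setpoint_tol` degrees C of the hold temperature (the
#' median of the final quarter of the record); the time axis is re-zeroed at
#' the trim point and a message is emitted.
#'
#' @param path file path.
#' @param dialect optional named character vector mapping standard names to
#'   the file's headers, e.g. `c(time_min = "t", mass_mg = "m")`.
#' @param kind `"auto"` (default), `"isothermal"` or `"nonisothermal"`.
#' @param heating_rate heating rate in degrees C/min for nonisothermal files
#'   without a time column; estimated from the time column when present.
#' @param setpoint_tol heat-up trimming tolerance, degrees C.
#' @return an `isothermal_run` or `nonisothermal_run`.
#' @export
read_tg_table <- function(path, dialect = NULL,
                          kind = c("auto", "isothermal", "nonisothermal"),
                          heating_rate = NULL, setpoint_tol = 0.5) {
  kind <- match.arg(kind)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) < 5L) stop("TG file ", path, " has fewer than 5 data rows")
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      hit <- match(dialect[[std]], names(df))
      if (is.na(hit)) stop("dialect column '", dialect[[std]], "' not found in ", path)
      names(df)[hit] <- std
    }
  }
  has_time <- "time_min" %in% names(df)
  has_temp <- "temp_C" %in% names(df)
  if (!"mass_mg" %in% names(df)) stop("missing required column mass_mg in ", path)
  if (!has_time && !has_temp) stop("need at least one of time_min / temp_C in ", path)

  if (kind == "auto") {
    ## an isothermal record spends most of its rows at the hold temperature
    ## (possibly after a heat-up ramp); a ramp record keeps rising
    if (!has_temp) {
      kind <- "isothermal"
    } else {
      hold <- stats::median(df$temp_C[seq(ceiling(0.75 * nrow(df)), nrow(df))])
      frac_at_hold <- mean(abs(df$temp_C - hold) <= 1)
      kind <- if (frac_at_hold > 0.3) "isothermal" else "nonisothermal"
    }
  }

  if (kind == "isothermal") {
    if (!has_time) stop("isothermal file ", path, " lacks a time_min column")
    if (has_temp) {
      setpoint <- stats::median(df$temp_C[df$temp_C >= stats::quantile(df$temp_C, 0.75)])
      at_hold <- which(abs(df$temp_C - setpoint) <= setpoint_tol)
      if (length(at_hold) == 0L) stop("no samples within ", setpoint_tol,
                                      " degrees C of the hold temperature in ", path)
      if (at_hold[1] > 1L) {
        message(sprintf("trimmed %d heat-up rows before the %.1f degC hold in %s",
                        at_hold[1] - 1L, setpoint, basename(path)))
        df <- df[at_hold[1]:nrow(df), , drop = FALSE]
      }
      temp <- setpoint
    } else {
      temp <- NA_real_
    }
    isothermal_run(temperature_C = temp,
                   time_min = df$time_min - df$time_min[1],
                   mass_mg = df$mass_mg, label = basename(path))
  } else {
    if (!has_temp) stop("nonisothermal file ", path, " lacks a temp_C column")
    if (is.null(heating_rate)) {
      if (!has_time) stop("supply heating_rate for nonisothermal file without time column: ", path)
      heating_rate <- stats::coef(stats::lm(temp_C ~ time_min, data = df))[[2]]
    }
    nonisothermal_run(heating_rate = heating_rate, temperature_C = df$temp_C,
                      mass_mg = df$mass_mg, label = basename(path),
                      time_min = if (has_time) df$time_min else NULL)
  }
}

#' Write a TG run to delimited text
#'
#' Writes the format [read_tg_table()] reads (full double precision, so a
#' write/read round trip is lossless well below 1e-9).
#'
#' @param run an `isothermal_run` or `nonisothermal_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tg_table <- function(run, path) {
  df <- if (inherits(run, "isothermal_run")) {
    data.frame(time_min = run$time_min,
               temp_C = rep(kelvin_to_celsius(run$temperature_K), length(run$time_min)),
               mass_mg = run$mass_mg)
  } else if (inherits(run, "nonisothermal_run")) {
    out <- data.frame(temp_C = kelvin_to_celsius(run$temperature_K),
                      mass_mg = run$mass_mg)
    if (!is.null(run$time_min)) out <- cbind(time_min = run$time_min, out)
    out
  } else {
    stop("run must be an isothermal_run or nonisothermal_run")
  }
  df[] <- lapply(df, function(x) formatC(x, digits = 17, format = "g"))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the temperature window of one decomposition step
#'
#' Validates that a temperature interval lies within the span of a
#' nonisothermal run and returns it. The default window for the packaged
#' Mn-porphyrin-like fixtures is 134-279 degrees C, the interval in which the
#' N-dealkylation step is the prevalent mass-loss process.
#'
#' @param run a `nonisothermal_run`.
#' @param window_C temperature interval in degrees Celsius, length 2.
#' @return the accepted interval (degrees C).
#' @export
select_step_window <- function(run, window_C = c(134, 279)) {
  stopifnot(inherits(run, "nonisothermal_run"), length(window_C) == 2L)
  window_C <- sort(window_C)
  span <- kelvin_to_celsius(range(run$temperature_K))
  if (window_C[1] < span[1] - 1e-9 || window_C[2] > span[2] + 1e-9) {
    stop(sprintf("window [%g, %g] degC outside the run's span [%g, %g] degC",
                 window_C[1], window_C[2], span[1], span[2]))
  }
  window_C
}

#' Compute the conversion degree of a decomposition step
#'
#' alpha = (m0 - m_t) / (m0 - mf), with m0 and mf taken at the window
#' boundaries so that a single step is isolated from a multi-step mass curve.
#' alpha is clipped to `[0, 1]` after the baseline is fixed.
#'
#' When a run ends before the step completes (typical of accelerated
#' isothermal holds), the boundary mass is NOT the step's final mass:
#' normalising to it would silently rescale alpha and destroy the rate
#' information. Supply the known step plateau as `mf` (e.g. from a complete
#' dynamic run of the same step) in that case; the resulting curve is
#' flagged partial.
#'
#' @param run an `isothermal_run` or `nonisothermal_run`.
#' @param window step window: temperature interval in degrees C
#'   (nonisothermal) or time interval in minutes (isothermal); `NULL` uses
#'   the full record.
#' @param min_loss_frac minimum mass loss within the window, as a fraction of
#'   m0, below which the step is considered degenerate.
#' @param m0,mf explicit baseline masses in mg, overriding the window
#'   boundary masses.
#' @return a `conversion_curve`.
#' @export
compute_conversion <- function(run, window = NULL, min_loss_frac = 0.005,
                               m0 = NULL, mf = NULL) {
  if (inherits(run, "nonisothermal_run")) {
    window <- if (is.null(window)) kelvin_to_celsius(range(run$temperature_K))
              else select_step_window(run, window)
    wK <- celsius_to_kelvin(window)
    keep <- run$temperature_K >= wK[1] - 1e-9 & run$temperature_K <= wK[2] + 1e-9
    if (sum(keep) < 5L) stop("fewer than 5 samples inside the step window")
    Tk <- run$temperature_K[keep]
    m <- run$mass_mg[keep]
    abscissa <- Tk
    kindargs <- list(source_kind = "nonisothermal", heating_rate = run$heating_rate)
  } else if (inherits(run, "isothermal_run")) {
    window <- if (is.null(window)) range(run$time_min) else sort(window)
    keep <- run$time_min >= window[1] - 1e-12 & run$time_min <= window[2] + 1e-12
    if (sum(keep) < 5L) stop("fewer than 5 samples inside the time window")
    abscissa <- run$time_min[keep]
    m <- run$mass_mg[keep]
    kindargs <- list(source_kind = "isothermal", temperature_K = run$temperature_K)
  } else {
    stop("run must be an isothermal_run or nonisothermal_run")
  }
  if (is.null(m0)) m0 <- m[1]
  if (is.null(mf)) mf <- m[length(m)]
  if (abs(m0 - mf) < min_loss_frac * abs(m0)) {
    stop(sprintf("degenerate step: mass loss %.3g mg is below %.2g%% of m0",
                 abs(m0 - mf), 100 * min_loss_frac))
  }
  alpha <- (m0 - m) / (m0 - mf)
  if (min(alpha) < -0.02) {
    warning(sprintf("alpha drifts to %.3g below baseline before clipping", min(alpha)))
  }
  alpha <- pmin(pmax(alpha, 0), 1)
  ## gross-nonmonotonicity warning threshold adapted to the point noise so
  ## ordinary instrument scatter does not trip it
  noise_est <- stats::mad(diff(alpha)) / sqrt(2)
  do.call(conversion_curve,
          c(list(abscissa = abscissa, alpha = alpha, m0 = m0, mf = mf,
                 window = window,
                 monotone_tol = max(1e-3, 6 * noise_est)), kindargs))
}
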