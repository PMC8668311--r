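## Registry of classical integral solid-state kinetic models.
##
## Each model is the linearised rate law g(alpha) = k t + k0, where g is the
## integral form of 1/f(alpha) and f is the differential reaction model in
## d(alpha)/dt = k(T) f(alpha). The registry order is fixed so that weight
## vectors produced downstream are comparable across runs.

.model_registry <- local({
  mk <- function(code, type, g, g_inv, f, g_image, closed_inverse = TRUE) {
    structure(
      list(code = code, model_type = type, g = g, g_inverse = g_inv, f = f,
           g_image = g_image, closed_inverse = closed_inverse),
      class = "kinetic_model")
  }

  ## numeric inverse by root bracketing for the two models without a closed
  ## form (D2, D4). Near alpha = 0 the direct formulas cancel
  ## catastrophically (g ~ c alpha^2 while the naive evaluation subtracts
  ## O(1) terms), so small values invert through the series
  ## g = c a^2 (1 + d a + ...), i.e. a = sqrt(y/c) (1 - d sqrt(y/c) / 2).
  num_inv <- function(g, c2, d3) {
    lb <- 1e-3
    ub <- 1 - 1e-15
    g_lb <- g(lb)
    function(y) {
      g_ub <- g(ub)
      vapply(y, function(yy) {
        if (yy <= g_lb) {
          a <- sqrt(max(yy, 0) / c2)
          return(a * (1 - d3 * a / 2))
        }
        if (yy >= g_ub) return(ub)
        stats::uniroot(function(a) g(a) - yy, lower = lb, upper = ub,
                       tol = 1e-14, extendInt = "no")$root
      }, numeric(1))
    }
  }

  avrami <- function(m) {
    mk(paste0("Am", m), "Avrami-Erofeev",
       g = function(a) (-log1p(-a))^(1 / m),
       g_inv = function(y) -expm1(-(y^m)),
       f = function(a) m * (1 - a) * (-log1p(-a))^(1 - 1 / m),
       g_image = c(0, Inf))
  }

  g_D2 <- function(a) (1 - a) * log1p(-a) + a
  g_D4 <- function(a) 1 - (2 / 3) * a - (1 - a)^(2 / 3)

  models <- list(
    mk("F1", "Chaotic nucleoid",
       g = function(a) -log1p(-a),
       g_inv = function(y) -expm1(-y),
       f = function(a) 1 - a,
       g_image = c(0, Inf)),
    avrami(2), avrami(3), avrami(4),
    mk("Au", "Avrami-Erofeev",
       g = function(a) log(a / (1 - a)),
       g_inv = function(y) stats::plogis(y),
       f = function(a) a * (1 - a),
       g_image = c(-Inf, Inf)),
    mk("R1", "Linear contraction",
       g = function(a) a,
       g_inv = function(y) y,
       f = function(a) rep_len(1, length(a)),
       g_image = c(0, 1)),
    mk("R2", "Area contraction",
       g = function(a) 1 - (1 - a)^(1 / 2),
       g_inv = function(y) 1 - (1 - y)^2,
       f = function(a) 2 * (1 - a)^(1 / 2),
       g_image = c(0, 1)),
    mk("R3", "Volume contraction",
       g = function(a) 1 - (1 - a)^(1 / 3),
       g_inv = function(y) 1 - (1 - y)^3,
       f = function(a) 3 * (1 - a)^(2 / 3),
       g_image = c(0, 1)),
    mk("D1", "One-dimension diffusion",
       g = function(a) a^2,
       g_inv = function(y) sqrt(y),
       f = function(a) 1 / (2 * a),
       g_image = c(0, 1)),
    mk("D2", "Two-dimension diffusion",
       g = g_D2,
       g_inv = num_inv(g_D2, c2 = 1 / 2, d3 = 1 / 3),
       f = function(a) -1 / log1p(-a),
       g_image = c(0, 1), closed_inverse = FALSE),
    mk("D3", "Three-dimension diffusion",
       g = function(a) (1 - (1 - a)^(1 / 3))^2,
       g_inv = function(y) 1 - (1 - sqrt(y))^3,
       f = function(a) (3 / 2) * (1 - a)^(2 / 3) / (1 - (1 - a)^(1 / 3)),
       g_image = c(0, 1)),
    mk("D4", "Ginstling-Brounshtein",
       g = g_D4,
       g_inv = num_inv(g_D4, c2 = 1 / 9, d3 = 4 / 9),
       f = function(a) (3 / 2) / ((1 - a)^(-1 / 3) - 1),
       g_image = c(0, 1 / 3), closed_inverse = FALSE)
  )
  names(models) <- vapply(models, `[[`, character(1), "code")
  models
})

#' Codes of the ten kinetic models used in the ensemble combiner
#' @export
TEN_MODEL_SET <- c("Am2", "Am4", "Au", "R1", "R2", "R3", "D1", "D2", "D3", "D4")

#' Codes of the full twelve-model registry, in registry order
#' @export
ALL_MODEL_CODES <- c("F1", "Am2", "Am3", "Am4", "Au", "R1", "R2", "R3",
                     "D1", "D2", "D3", "D4")

#' List solid-state kinetic models
#'
#' Returns kinetic model objects from the fixed twelve-model registry
#' (nucleation F1, Avrami-Erofeev Am2/Am3/Am4 and autocatalytic Au, geometric
#' contraction R1/R2/R3, diffusion D1-D4 including Ginstling-Brounshtein).
#' The default subset is the ten-model set used by the ensemble combiner;
#' the full registry is available by passing [ALL_MODEL_CODES].
#'
#' Requested codes are returned in registry order regardless of the order
#' given, so downstream weight vectors are reproducible.
#'
#' @param codes character vector of model codes, or `NULL` for the default
#'   ten-model set.
#' @return named list of `kinetic_model` objects, in registry order.
#' @examples
#' names(kinetic_models())              # the ten-model set
#' kinetic_models("R2")[["R2"]]$g(0.75) # 0.5
#' @export
kinetic_models <- function(codes = NULL) {
  if (is.null(codes)) codes <- TEN_MODEL_SET
  unknown <- setdiff(codes, names(.model_registry))
  if (length(unknown)) {
    stop("unknown kinetic model code(s): ", paste(unknown, collapse = ", "))
  }
  .model_registry[intersect(names(.model_registry), codes)]
}

#' Fetch a single kinetic model by code
#' @param code model code, e.g. `"R2"`.
#' @return a `kinetic_model` object.
#' @export
kinetic_model <- function(code) {
  kinetic_models(code)[[1]]
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model %s: %s>\n", x$code, x$model_type))
  invisible(x)
}

.check_alpha_domain <- function(model, alpha, eps = 0) {
  lo <- eps
  hi <- 1 - eps
  bad <- !is.finite(alpha) | alpha <= lo | alpha >= hi
  if (any(bad)) {
    stop(sprintf("alpha outside the open domain (%g, %g) for model %s: first offending value %g",
                 lo, hi, model$code, alpha[which(bad)[1]]))
  }
  invisible(TRUE)
}

#' Integral form g(alpha) of a kinetic model
#'
#' @param model a `kinetic_model` or model code.
#' @param alpha conversion degree(s) strictly inside (0, 1).
#' @return g(alpha); under isothermal conditions g(alpha) = k t + k0.
#' @export
g_of_alpha <- function(model, alpha) {
  if (is.character(model)) model <- kinetic_model(model)
  .check_alpha_domain(model, alpha)
  model$g(alpha)
}

#' Inverse of the integral form, alpha(g)
#'
#' Maps a value of the integral form back to a conversion degree. Values
#' outside the image of g over (0, 1) either raise an error (default) or are
#' clipped to the image boundary, which is the behaviour the ensemble
#' combiner uses for its hidden-layer activation.
#'
#' @param model a `kinetic_model` or model code.
#' @param y value(s) of g.
#' @param policy `"error"` or `"clip"` for values outside the image of g.
#' @param eps domain clip used when `policy = "clip"`; results are confined
#'   to the conversion range `[eps, 1 - eps]`.
#' @return conversion degree(s) in (0, 1).
#' @export
alpha_of_g <- function(model, y, policy = c("error", "clip"), eps = 1e-9) {
  if (is.character(model)) model <- kinetic_model(model)
  policy <- match.arg(policy)
  ## only transforms that diverge at an endpoint need the eps guard; models
  ## whose g is finite on the closed interval invert exactly at 0 and 1
  a_lo <- if (is.finite(model$g(0))) 0 else eps
  a_hi <- if (!model$closed_inverse) 1 - max(eps, 1e-12)
          else if (is.finite(model$g(1))) 1
          else 1 - eps
  lo <- model$g(a_lo)
  hi <- model$g(a_hi)
  out_of_image <- !is.finite(y) | y < lo | y > hi
  if (any(out_of_image)) {
    if (policy == "error") {
      stop(sprintf("value %g outside the image of g for model %s",
                   y[which(out_of_image)[1]], model$code))
    }
    y <- pmin(pmax(y, lo), hi)
  }
  model$g_inverse(y)
}

#' Differential form f(alpha) of a kinetic model
#'
#' f(alpha) = 1 / (dg/dalpha) is the reaction model entering the rate law
#' d(alpha)/dt = k(T) f(alpha).
#'
#' @inheritParams g_of_alpha
#' @return f(alpha), positive on the interior of the domain.
#' @export
f_of_alpha <- function(model, alpha) {
  if (is.character(model)) model <- kinetic_model(model)
  .check_alpha_domain(model, alpha)
  model$f(alpha)
}
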