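## Fixed-hidden-weight MLP ensemble of kinetic models.
##
## One hidden neuron per kinetic model: its incoming weight and bias are the
## rate constant k and intercept k0 of that model's linearised isothermal fit
## g(alpha) = k t + k0 (predetermined, never trained). The hidden activation
## is the model's g-inverse, so each hidden state is that model's predicted
## alpha(t) in [0, 1]. Only the output layer is solved, in closed form, by
## the pseudo-inverse: w2 = (B'B)^-1 B' alpha_exp with B = f(w1 x). The
## normalised |w2| are the per-model contributions.

#' Linearised fit of one kinetic model to an isothermal curve
#'
#' Ordinary least squares of g(alpha) on time gives the rate constant k
#' (slope, 1/min in g-units) and intercept k0. The reported residual is the
#' mean squared error of the model's alpha reconstruction (after the inverse
#' transform), so residuals are comparable across models.
#'
#' @param model `kinetic_model` or code.
#' @param curve an isothermal `conversion_curve`.
#' @param clip_eps conversions are clipped into `[clip_eps, 1 - clip_eps]`
#'   before g is applied, keeping divergent transforms (Au, F1, Am) finite.
#' @return a `model_fit` list: `code`, `k`, `k0`, `residual`, `temperature_K`,
#'   `n_points`.
#' @export
fit_model_linear <- function(model, curve, clip_eps = 1e-6) {
  if (is.character(model)) model <- kinetic_model(model)
  stopifnot(inherits(curve, "conversion_curve"))
  if (!identical(curve$source_kind, "isothermal")) {
    stop("fit_model_linear expects an isothermal conversion curve")
  }
  t <- curve$abscissa
  ## clip only the endpoints where the model's transform diverges
  lo <- if (is.finite(model$g(0))) 0 else clip_eps
  hi <- if (is.finite(model$g(1))) 1 else 1 - clip_eps
  a_clip <- pmin(pmax(curve$alpha, lo), hi)
  g <- model$g(a_clip)
  usable <- is.finite(g)
  if (sum(usable) < 3L) {
    stop("fewer than 3 usable points after clipping for model ", model$code)
  }
  fit <- stats::lm.fit(cbind(1, t[usable]), g[usable])
  k0 <- fit$coefficients[[1]]
  k <- fit$coefficients[[2]]
  a_hat <- alpha_of_g(model, k * t + k0, policy = "clip", eps = clip_eps)
  structure(
    list(code = model$code, k = k, k0 = k0,
         residual = mean((a_hat - curve$alpha)^2),
         temperature_K = curve$temperature_K, n_points = sum(usable)),
    class = "model_fit")
}

#' Hidden-state matrix B of the fixed-weight MLP
#'
#' For hidden neuron i (kinetic model i with fitted weights k_i, k0_i) the
#' pre-activation at time t is `k_i t + k0_i`; the activation is the model's
#' g-inverse clipped to `[0, 1]`, so column i of B is model i's predicted
#' conversion curve. Rows are time points, columns follow the fit order
#' (registry order).
#'
#' @param fits list of `model_fit`s (one per hidden neuron).
#' @param times minute grid.
#' @param clip_eps activation clip, as in [fit_model_linear()].
#' @return numeric matrix B, `length(times)` x `length(fits)`, with model
#'   codes as column names.
#' @export
build_hidden_states <- function(fits, times, clip_eps = 1e-6) {
  stopifnot(length(fits) > 0L, length(times) > 0L)
  B <- vapply(fits, function(ft) {
    model <- kinetic_model(ft$code)
    pre <- ft$k * times + ft$k0
    pmin(pmax(alpha_of_g(model, pre, policy = "clip", eps = clip_eps), 0), 1)
  }, numeric(length(times)))
  B <- matrix(B, nrow = length(times))
  colnames(B) <- vapply(fits, `[[`, character(1), "code")
  flat <- apply(B, 2, function(col) diff(range(col)) < 1e-12)
  if (any(flat)) {
    warning("all-constant hidden column(s): ",
            paste(colnames(B)[flat], collapse = ", "))
  }
  B
}

#' Output weights by the pseudo-inverse
#'
#' Solves the output layer of the fixed-weight MLP in closed form,
#' `w2 = (B'B)^-1 B' alpha_exp`, minimising the reconstruction energy
#' `||B w2 - alpha_exp||^2`. When the normal-equations condition number
#' exceeds `cond_tol` (near-collinear model columns, e.g. R1 vs R2), the
#' minimum-norm least-squares solution via SVD is used instead and the
#' condition number is reported in a message.
#'
#' @param B hidden-state matrix (rows = observations).
#' @param alpha_exp observed conversions, `length(alpha_exp) == nrow(B)`.
#' @param cond_tol condition-number threshold for the SVD fallback.
#' @return numeric weight vector w2 (may contain negative entries).
#' @export
solve_output_weights <- function(B, alpha_exp, cond_tol = 1e10) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == length(alpha_exp))
  G <- crossprod(B)
  cond <- kappa(G, exact = TRUE)
  if (!is.finite(cond) || cond > cond_tol) {
    message(sprintf("normal equations ill-conditioned (kappa = %.3g); using minimum-norm SVD solution", cond))
    sv <- svd(B)
    tol <- max(dim(B)) * .Machine$double.eps * sv$d[1]
    pos <- sv$d > tol
    w2 <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], alpha_exp)) / sv$d[pos])
    w2 <- drop(w2)
  } else {
    w2 <- drop(solve(G, crossprod(B, alpha_exp)))
  }
  names(w2) <- colnames(B)
  w2
}

#' Ensemble combination of kinetic models on one isothermal curve
#'
#' Full fixed-weight MLP pass: per-model linearised fits, hidden-state
#' matrix, pseudo-inverse output weights, mean squared reconstruction error,
#' and normalised per-model contributions `|w2_i| / sum_j |w2_j|`.
#'
#' @param curve an isothermal `conversion_curve`.
#' @param codes model codes; default the ten-model set.
#' @param clip_eps conversion clip for divergent transforms.
#' @param cond_tol passed to [solve_output_weights()].
#' @return a `combination_result`: `fits`, `w2`, `residual_error`,
#'   `contributions`, `temperature_K`, `reconstruction`.
#' @export
combination_report <- function(curve, codes = TEN_MODEL_SET, clip_eps = 1e-6,
                               cond_tol = 1e10) {
  models <- kinetic_models(codes)
  fits <- lapply(models, fit_model_linear, curve = curve, clip_eps = clip_eps)
  B <- build_hidden_states(fits, curve$abscissa, clip_eps = clip_eps)
  w2 <- solve_output_weights(B, curve$alpha, cond_tol = cond_tol)
  recon <- drop(B %*% w2)
  contributions <- abs(w2) / sum(abs(w2))
  structure(
    list(fits = fits, w2 = w2,
         residual_error = mean((recon - curve$alpha)^2),
         contributions = contributions,
         temperature_K = curve$temperature_K,
         reconstruction = recon),
    class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("<combination_result at %.2f K: residual %.3g>\n",
              x$temperature_K, x$residual_error))
  df <- as.data.frame(x)
  print(df[order(-df$contribution), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.combination_result <- function(x, ...) {
  data.frame(
    model = names(x$w2),
    k = vapply(x$fits, `[[`, numeric(1), "k"),
    k0 = vapply(x$fits, `[[`, numeric(1), "k0"),
    residual = vapply(x$fits, `[[`, numeric(1), "residual"),
    w2 = unname(x$w2),
    contribution = unname(x$contributions),
    row.names = NULL
  )
}

#' Residual of each kinetic model fitted alone
#'
#' Fits every model in `codes` individually to the curve and returns the
#' alpha-space mean squared residuals, with the implied ranking. Comparable
#' residuals across several models signal that the decomposition is better
#' described by a combination of mechanisms than by any single one.
#'
#' @inheritParams combination_report
#' @return data.frame (model, residual, rank), in registry order.
#' @export
per_model_residuals <- function(curve, codes = TEN_MODEL_SET, clip_eps = 1e-6) {
  fits <- lapply(kinetic_models(codes), fit_model_linear,
                 curve = curve, clip_eps = clip_eps)
  res <- vapply(fits, `[[`, numeric(1), "residual")
  data.frame(model = names(res), residual = unname(res),
             rank = rank(res, ties.method = "min"), row.names = NULL)
}
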