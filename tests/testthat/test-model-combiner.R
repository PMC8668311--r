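test_that("linearised fits are exact on exact model data", {
  # R1: alpha = 0.01 t
  cc <- conversion_curve(0:60, pmin(0.01 * (0:60), 1), "isothermal",
                         temperature_K = 433.15)
  ft <- fit_model_linear("R1", cc)
  expect_equal(ft$k, 0.01, tolerance = 1e-12)
  expect_equal(ft$k0, 0, tolerance = 1e-12)
  # R2 data generated with k = 0.005, k0 = 0: linearisation is exact
  a <- alpha_of_g("R2", 0.005 * (0:60), policy = "clip")
  cc2 <- conversion_curve(0:60, a, "isothermal", temperature_K = 433.15)
  ft2 <- fit_model_linear("R2", cc2)
  expect_equal(ft2$k, 0.005, tolerance = 1e-10)
  expect_equal(ft2$k0, 0, tolerance = 1e-10)
  expect_error(fit_model_linear("R1", conversion_curve(0:1 + 0.0, c(0, 0.5),
                                                      "isothermal")),
               "at least 5|usable")
})

test_that("hidden states are each model's predicted conversion in [0, 1]", {
  fits <- list(list(code = "R1", k = 0.01, k0 = 0))
  B <- build_hidden_states(fits, times = c(0, 10, 50, 200))
  expect_equal(unname(B[2, 1]), 0.1)
  expect_equal(unname(B[4, 1]), 1)  # clipped at the activation ceiling
  expect_true(all(B >= 0 & B <= 1))

  curve <- fx_iso_curves("R2")[[1]]
  fit <- fit_model_linear("R2", curve)
  B2 <- build_hidden_states(list(fit), curve$abscissa)
  # column equals the forward-simulated curve for the matching rate constant
  expect_lt(max(abs(B2[, 1] - curve$alpha)), 1e-7)
  expect_warning(build_hidden_states(list(list(code = "R1", k = 0, k0 = 0.5)),
                                     0:10),
                 "constant")
})

test_that("pseudo-inverse output weights match a QR least-squares oracle", {
  set.seed(42)
  for (rep in 1:5) {
    B <- matrix(stats::rnorm(50 * 4), 50, 4)
    y <- stats::rnorm(50)
    w <- solve_output_weights(B, y)
    oracle <- qr.solve(B, y)
    expect_lt(max(abs(w - oracle)), 1e-8)
  }
  # single column equal to the data -> weight 1
  y <- seq(0, 1, length.out = 20)
  expect_equal(unname(solve_output_weights(matrix(y), y)), 1, tolerance = 1e-12)
  # orthonormal columns -> w2 = B' y
  Q <- qr.Q(qr(matrix(stats::rnorm(30 * 3), 30, 3)))
  y <- stats::rnorm(30)
  expect_equal(unname(solve_output_weights(Q, y)), drop(crossprod(Q, y)),
               tolerance = 1e-10)
})

test_that("real model-column systems agree with the oracle too", {
  curve <- fx_iso_curves("R1", noise_sd = 0.002, seed_base = 300L)[[1]]
  fits <- lapply(kinetic_models(c("R1", "R3", "D1", "Au")), fit_model_linear,
                 curve = curve)
  B <- build_hidden_states(fits, curve$abscissa)
  w <- solve_output_weights(B, curve$alpha)
  expect_lt(max(abs(w - qr.solve(B, curve$alpha))), 1e-8)
})

test_that("energy optimality: no single-coordinate perturbation improves w2", {
  curve <- fx_iso_curves("R2", noise_sd = 0.002, seed_base = 310L)[[1]]
  co <- suppressMessages(combination_report(curve, codes = c("R1", "R2", "Au", "D1")))
  B <- build_hidden_states(co$fits, curve$abscissa)
  energy <- function(w) sum((drop(B %*% w) - curve$alpha)^2)
  e0 <- energy(co$w2)
  for (i in seq_along(co$w2)) {
    for (d in c(-1e-3, 1e-3)) {
      w <- co$w2
      w[i] <- w[i] + d
      expect_gte(energy(w), e0)
    }
  }
})

test_that("noiseless single-model data is reconstructed to machine accuracy", {
  curve <- fx_iso_curves("R1")[[1]]
  co <- suppressMessages(combination_report(curve))
  expect_lt(co$residual_error, 1e-10)
  expect_equal(sum(co$contributions), 1, tolerance = 1e-12)
  # generating model carries the largest contribution in the noiseless limit
  expect_equal(max(co$contributions), co$contributions[["R1"]], tolerance = 1e-6)
})

test_that("noisy reconstruction residual is of the order of the noise variance", {
  curve <- fx_iso_curves("R1", noise_sd = 0.002, seed_base = 320L)[[1]]
  co <- suppressMessages(combination_report(curve))
  expect_lt(co$residual_error, 10 * 0.002^2)
  expect_gt(co$residual_error, 0.01 * 0.002^2)
})

test_that("per-model residuals rank the generating model first", {
  for (code in c("R1", "Au", "D3")) {
    curve <- fx_iso_curves(code, noise_sd = 0.002, seed_base = 330L)[[1]]
    pr <- per_model_residuals(curve)
    expect_true(all(pr$residual >= 0))
    expect_equal(pr$model[pr$rank == 1], code, label = code)
  }
})

test_that("noise inflates the residual of well-specified fits by the noise variance", {
  # For the generating model the clean residual is at machine level, so the
  # noisy residual must land near sigma^2 (1 - 2/n). (Structurally misfit
  # models do not obey a clean ordering: their residual is dominated by
  # lack-of-fit, which refitting under clipped noise can nudge either way.)
  clean <- fx_iso_curves("R2")[[1]]
  res_clean <- per_model_residuals(clean)
  res_clean_r2 <- res_clean$residual[res_clean$model == "R2"]
  sig2 <- 0.002^2 * (1 - 2 / 61)
  for (s in 1:5) {
    pr <- per_model_residuals(fx_iso_curves("R2", noise_sd = 0.002,
                                            seed_base = 400L + 10L * s)[[1]])
    r2 <- pr$residual[pr$model == "R2"]
    expect_gt(r2, res_clean_r2)
    expect_lt(abs(r2 - sig2) / sig2, 1)  # within a factor of two
  }
})

test_that("brute-force normal equations agree with the solver on small systems", {
  curve <- fx_iso_curves("R3", noise_sd = 0.002, seed_base = 350L)[[1]]
  keep <- seq(1, 61, by = 2)  # <= 50 points
  small <- conversion_curve(curve$abscissa[keep], curve$alpha[keep], "isothermal",
                            temperature_K = curve$temperature_K,
                            monotone_tol = 0.02)
  fits <- lapply(kinetic_models(c("R1", "R2", "R3", "Au")), fit_model_linear,
                 curve = small)
  B <- build_hidden_states(fits, small$abscissa)
  w <- solve_output_weights(B, small$alpha)
  brute <- solve(t(B) %*% B) %*% t(B) %*% small$alpha
  expect_lt(max(abs(w - drop(brute))), 1e-8)
})
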