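test_that("Arrhenius fit recovers exact parameters and is scale-consistent", {
  Ea <- 100e3; lnA <- 20
  T2 <- c(420, 440)
  k2 <- exp(lnA - Ea / (8.314 * T2))
  fit2 <- arrhenius_fit("R1", T2, k2)
  expect_equal(fit2$Ea, Ea, tolerance = 1e-9)
  expect_equal(fit2$lnA, lnA, tolerance = 1e-9)

  T4 <- seq(431.15, 437.15, by = 2)
  k4 <- exp(lnA - Ea / (8.314 * T4))
  fit4 <- arrhenius_fit("R1", T4, k4)
  expect_equal(fit4$Ea, Ea, tolerance = 1e-9)
  expect_equal(fit4$lnA, lnA, tolerance = 1e-9)

  # doubling every k leaves Ea, shifts lnA by log(2)
  fit_scaled <- arrhenius_fit("R1", T4, 2 * k4)
  expect_equal(fit_scaled$Ea, fit4$Ea, tolerance = 1e-9)
  expect_equal(fit_scaled$lnA, fit4$lnA + log(2), tolerance = 1e-9)

  expect_error(arrhenius_fit("R1", 431.15, 0.01), "2 distinct")
  expect_error(arrhenius_fit("R1", T2, c(0.01, -1)), "positive")
})

test_that("rate constant queries reproduce training points and identities", {
  Ea <- 95e3; lnA <- 21
  T4 <- seq(431.15, 437.15, by = 2)
  fit <- arrhenius_fit("R1", T4, exp(lnA - Ea / (8.314 * T4)))
  expect_equal(rate_constant_at(fit, 431.15),
               exp(lnA - Ea / (8.314 * 431.15)), tolerance = 1e-9)
  # k(T1)/k(T2) identity
  r <- rate_constant_at(fit, 298.15) / rate_constant_at(fit, 431.15)
  expect_equal(r, exp(-Ea / 8.314 * (1 / 298.15 - 1 / 431.15)), tolerance = 1e-9)
  expect_equal(rate_constant_at(fit, 1e12), exp(lnA), tolerance = 1e-3)
})

test_that("t90 closed forms, unit discipline, and temperature monotonicity", {
  fit <- arrhenius_fit("R1", c(420, 440), exp(20 - 100e3 / (8.314 * c(420, 440))))
  # override k via a two-point fit pinned to k = 0.001 at both ends
  fit_k <- arrhenius_fit("R1", c(420, 440), c(0.001, 0.001) * exp(c(0, 1e-12)))
  e_r1 <- t90_shelf_life("R1", fit_k, 430)
  expect_equal(e_r1$t90_min, 0.1 / e_r1$k_at_T, tolerance = 1e-9)
  expect_equal(e_r1$t90_min, 100, tolerance = 1e-6)
  e_r2 <- t90_shelf_life("R2", fit_k, 430)
  expect_equal(e_r2$t90_min, (1 - sqrt(0.9)) / e_r2$k_at_T, tolerance = 1e-9)
  expect_equal(e_r2$t90_min, 51.32, tolerance = 1e-3)
  # years * 525600 == minutes
  expect_equal(e_r2$t90_years * 525600, e_r2$t90_min, tolerance = 1e-9)
  # t90 strictly increases as temperature decreases, for every model
  for (code in setdiff(TEN_MODEL_SET, "Au")) {
    t90s <- vapply(c(450, 400, 350, 298.15), function(Tq) {
      t90_shelf_life(code, fit, Tq)$t90_min
    }, numeric(1))
    expect_true(all(diff(t90s) > 0), label = code)
  }
  # t90(25C)/t90(158C) equals the inverse rate-constant ratio
  r <- t90_shelf_life("R3", fit, 298.15)$t90_min /
       t90_shelf_life("R3", fit, 431.15)$t90_min
  expect_equal(r, rate_constant_at(fit, 431.15) / rate_constant_at(fit, 298.15),
               tolerance = 1e-9)
  # Au has no positive g(0.10): entry is NA with a warning
  expect_warning(e_au <- t90_shelf_life("Au", fit, 430), "ill-defined")
  expect_true(is.na(e_au$t90_min))
})

test_that("shelf-life table has the per-model structure across temperatures", {
  combos <- lapply(fx_iso_curves("R1", noise_sd = 0.002, seed_base = 500L),
                   function(cc) suppressMessages(combination_report(cc)))
  slt <- shelf_life_table(combos)
  expect_equal(nrow(slt), 10L)
  expect_setequal(slt$model, TEN_MODEL_SET)
  expect_true(all(c("Ea_kJ_mol", "ln_A", "t90_158C_h", "t90_25C_years")
                  %in% names(slt)))
  ok <- slt$model != "Au" & !is.na(slt$Ea_kJ_mol)
  expect_true(all(slt$t90_25C_years[ok] > slt$t90_158C_h[ok] / 8760))
})

test_that("raising every isotherm temperature raises every fitted rate constant", {
  ar <- fx_iso_arrhenius("R1")
  k_at <- function(shift) {
    combos <- lapply(c(158, 160, 162, 164) + shift, function(Tc) {
      cc <- simulate_isothermal("R1", ar, Tc, times = 0:60)
      suppressMessages(combination_report(cc))
    })
    vapply(combos[[1]]$fits, `[[`, numeric(1), "k")
  }
  expect_true(all(k_at(2) > k_at(0)))
})

test_that("end-to-end chain reproduces the generating shelf life", {
  ar <- fx_iso_arrhenius("R1")
  truth_t90_25C <- 0.1 / rate_k(ar, celsius_to_kelvin(25))
  # noiseless: whole chain exact to 0.1%
  combos0 <- lapply(fx_iso_curves("R1"),
                    function(cc) suppressMessages(combination_report(cc)))
  r1_0 <- shelf_life_table(combos0)[4, ]  # R1 row (registry order)
  expect_equal(r1_0$model, "R1")
  expect_lt(abs(r1_0$Ea_kJ_mol * 1e3 - ISO_EA) / ISO_EA, 1e-3)
  expect_lt(abs(r1_0$t90_25C_years * 525600 - truth_t90_25C) / truth_t90_25C, 1e-3)
  # noise sd 0.002: Ea and lnA within 5%, t90 within 10%
  combos <- lapply(fx_iso_curves("R1", noise_sd = 0.002, seed_base = 600L),
                   function(cc) suppressMessages(combination_report(cc)))
  r1 <- shelf_life_table(combos)[4, ]
  expect_lt(abs(r1$Ea_kJ_mol * 1e3 - ISO_EA) / ISO_EA, 0.05)
  expect_lt(abs(r1$ln_A - ar$lnA) / abs(ar$lnA), 0.05)
  expect_lt(abs(r1$t90_25C_years * 525600 - truth_t90_25C) / truth_t90_25C, 0.10)
})
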