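test_that("run constructors validate their invariants", {
  expect_error(isothermal_run(160, time_min = c(0, 1, 2, 2, 4), mass_mg = rep(2, 5)),
               "strictly increasing")
  expect_error(isothermal_run(160, time_min = 0:3, mass_mg = rep(2, 4)),
               "at least 5")
  expect_error(nonisothermal_run(10, temperature_C = c(30, 40, 35, 50, 60),
                                 mass_mg = rep(2, 5)),
               "row: 3")
  # time column inconsistent with the declared heating rate
  expect_error(nonisothermal_run(10, temperature_C = seq(30, 130, by = 20),
                                 mass_mg = rep(2, 6), time_min = 0:5),
               "inconsistent")
})

test_that("TG file round trip is lossless and autodetects the run kind", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  run <- isothermal_run(160, time_min = 0:60,
                        mass_mg = 3 - 0.5 * (0:60) / 60, label = "iso")
  write_tg_table(run, tmp)
  back <- read_tg_table(tmp)
  expect_s3_class(back, "isothermal_run")
  expect_equal(length(back$time_min), 61L)
  expect_lt(max(abs(back$mass_mg - run$mass_mg)), 1e-9)
  expect_lt(abs(back$temperature_K - run$temperature_K), 1e-9)

  ramp <- nonisothermal_run(10, temperature_C = seq(30, 600, by = 5),
                            mass_mg = seq(3, 2, length.out = 115))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_tg_table(ramp, tmp2)
  back2 <- read_tg_table(tmp2, heating_rate = 10)
  expect_s3_class(back2, "nonisothermal_run")
  expect_lt(max(abs(back2$mass_mg - ramp$mass_mg)), 1e-9)
})

test_that("dialect mapping and parse errors with row context", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,m", "0,3", "1,2.9", "2,2.8", "3,2.7", "4,2.6"), tmp)
  run <- read_tg_table(tmp, dialect = c(time_min = "t", mass_mg = "m"))
  expect_s3_class(run, "isothermal_run")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,mass_mg", "0,3", "1,2.9", "1,2.8", "3,2.7", "4,2.6"), bad)
  expect_error(read_tg_table(bad), "row: 3")
  nofile <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "2,3", "3,4", "4,5", "5,6"), nofile)
  expect_error(read_tg_table(nofile), "mass_mg")
})

test_that("isothermal heat-up ramp is trimmed to the hold temperature", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  temp <- c(seq(30, 160, by = 13), rep(160, 50))
  n <- length(temp)
  writeLines(c("time_min,temp_C,mass_mg",
               paste(seq_len(n) - 1, temp, 3 - 0.002 * seq_len(n), sep = ",")),
             tmp)
  expect_message(run <- read_tg_table(tmp), "trimmed")
  expect_equal(length(run$time_min), 51L)
  expect_equal(run$time_min[1], 0)
  expect_equal(kelvin_to_celsius(run$temperature_K), 160)
})

test_that("step window selection accepts in-span windows and rejects others", {
  run <- nonisothermal_run(10, temperature_C = seq(30, 600, by = 5),
                           mass_mg = seq(3, 2, length.out = 115))
  expect_equal(select_step_window(run), c(134, 279))
  expect_equal(select_step_window(run, c(30, 600)), c(30, 600))
  expect_error(select_step_window(run, c(700, 800)), "outside")
})

test_that("conversion recovers a planted alpha trace and honours the formula", {
  # generate mass = m0 - alpha * (m0 - mf) and invert
  m0 <- 3.0; mf <- 2.0
  alpha_true <- c(0, pnorm(seq(-2.5, 2.5, length.out = 59)), 1)
  alpha_true <- (alpha_true - alpha_true[1]) / (alpha_true[61] - alpha_true[1])
  run <- isothermal_run(160, time_min = 0:60,
                        mass_mg = m0 - alpha_true * (m0 - mf))
  cc <- compute_conversion(run)
  expect_lt(max(abs(cc$alpha - alpha_true)), 1e-9)
  expect_equal(cc$m0, m0)
  expect_equal(cc$mf, mf)
  expect_equal(cc$alpha[1], 0)
  expect_equal(cc$alpha[61], 1)
  # the point mass 2.5 maps to alpha 0.5
  run2 <- isothermal_run(160, time_min = 0:4, mass_mg = c(3, 2.8, 2.5, 2.2, 2))
  expect_equal(compute_conversion(run2)$alpha[3], 0.5)
})

test_that("conversion is invariant to affine mass rescaling (mg to ug)", {
  alpha_true <- seq(0, 1, length.out = 21)
  run_mg <- isothermal_run(160, time_min = 0:20, mass_mg = 3 - alpha_true)
  run_ug <- isothermal_run(160, time_min = 0:20, mass_mg = (3 - alpha_true) * 1000)
  expect_lt(max(abs(compute_conversion(run_mg)$alpha -
                    compute_conversion(run_ug)$alpha)), 1e-12)
})

test_that("explicit step-plateau baseline preserves the rate information", {
  # run ends at alpha 0.6: normalising to the record's final mass would
  # rescale alpha (and the fitted k) by 1/0.6; the known plateau must not
  alpha_true <- 0.01 * (0:60)  # R1, k = 0.01/min, ends at 0.6
  m0 <- 2.5; loss <- 0.58
  run <- isothermal_run(160, 0:60, m0 - loss * alpha_true)
  cc <- compute_conversion(run, mf = m0 - loss)
  expect_lt(max(abs(cc$alpha - alpha_true)), 1e-12)
  expect_true(cc$partial)
  k_fit <- fit_model_linear("R1", cc)$k
  expect_equal(k_fit, 0.01, tolerance = 1e-10)
  # without the baseline the curve is silently renormalised to the window
  cc_naive <- compute_conversion(run)
  expect_equal(fit_model_linear("R1", cc_naive)$k, 1 / 60, tolerance = 1e-10)
})

test_that("degenerate steps are rejected", {
  run <- isothermal_run(160, time_min = 0:9, mass_mg = rep(3, 10) + 1e-6 * (0:9))
  expect_error(compute_conversion(run), "degenerate")
})

test_that("nonisothermal conversion windows the mass curve at the step boundaries", {
  stages <- mn_porphyrin_stages()
  run <- simulate_tg_mass_curve(stages, m0 = 2.5, beta = 10)
  cc <- compute_conversion(run, window = c(134, 279))
  expect_identical(cc$source_kind, "nonisothermal")
  expect_equal(cc$alpha[1], 0)
  expect_equal(cc$alpha[length(cc$alpha)], 1)
  expect_true(all(diff(cc$alpha) > -1e-3))
})
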