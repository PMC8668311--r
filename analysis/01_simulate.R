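#!/usr/bin/env Rscript

# Step 1: build the synthetic TG study data.
#
# Nonisothermal arm: full three-stage mass curves (dehydration ->
# N-dealkylation -> ring decomposition) for a hydrated Mn-porphyrin-like
# sample at heating rates 5, 7.5, 10 and 12.5 degC/min over 30-600 degC,
# with 1 ug Gaussian mass noise. Stage stoichiometry comes from the
# molecular formula (octahydrate, four ethyl chlorides).
#
# Isothermal arm: four 60-minute runs at 158/160/162/164 degC generated
# from the R1 (linear contraction) model with Ea = 95.6 kJ/mol and alpha
# noise sd 0.002, written as mass curves with m0 = 2.5 mg.
#
# Raw traces go to scratch/fixtures/ (regenerable bulk data); later steps
# read them back through the package's TG parser.

suppressPackageStartupMessages(library(tgkinetics))

seed <- 20260101L
out <- "scratch/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

betas <- c(5, 7.5, 10, 12.5)
stages <- mn_porphyrin_stages(beta = 10)
cat("stage mass-loss fractions (from molar masses):\n")
for (s in stages) cat(sprintf("  %-18s %.4f (%s)\n", s$name,
                              s$mass_loss_fraction, s$model$code))

for (i in seq_along(betas)) {
  run <- simulate_tg_mass_curve(stages, m0 = 2.5, beta = betas[i],
                                noise_sd_mg = 1e-3, seed = seed + i)
  write_tg_table(run, file.path(out, sprintf("noniso_beta%g.csv", betas[i])))
}
cat(sprintf("wrote %d nonisothermal mass curves (beta = %s degC/min)\n",
            length(betas), paste(betas, collapse = ", ")))

iso_temps <- c(158, 160, 162, 164)
Ea <- 95.6e3
ar <- arrhenius_spec(Ea, lnA_for_isothermal("R1", Ea, max(iso_temps), 0.9, 60))
cat(sprintf("isothermal generator: R1, Ea = %.1f kJ/mol, lnA = %.3f (A in 1/min)\n",
            Ea / 1e3, ar$lnA))
for (i in seq_along(iso_temps)) {
  cc <- simulate_isothermal("R1", ar, iso_temps[i], times = 0:60,
                            noise_sd = 0.002, seed = seed + 100L + i)
  # render as a mass record: m0 2.5 mg, step loss 0.58 mg
  run <- isothermal_run(iso_temps[i], cc$abscissa, 2.5 - 0.58 * cc$alpha,
                        label = sprintf("iso %g C", iso_temps[i]))
  write_tg_table(run, file.path(out, sprintf("iso_%gC.csv", iso_temps[i])))
}
cat(sprintf("wrote %d isothermal runs at %s degC, 61 samples each\n",
            length(iso_temps), paste(iso_temps, collapse = "/")))
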