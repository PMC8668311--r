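# Canonical synthetic study conditions shared across the test files.
#
# Isothermal arm: four isotherms at 158/160/162/164 degC sampled once per
# minute for 60 min; Ea = 95.6 kJ/mol; lnA set so the generating model
# reaches alpha = 0.9 at the end of the hottest run (accelerated runs must
# not run to completion). Nonisothermal arm: R2, Ea = 100 kJ/mol,
# A = 1e10 1/min, heating rates 5/7.5/10/12.5 degC/min over 30-600 degC.

ISO_TEMPS_C <- c(158, 160, 162, 164)
ISO_EA <- 95.6e3
ISO_TIMES <- 0:60

NONISO_BETAS <- c(5, 7.5, 10, 12.5)
NONISO_EA <- 100e3
NONISO_LNA <- log(1e10)

fx_iso_arrhenius <- function(code) {
  arrhenius_spec(ISO_EA, lnA_for_isothermal(code, ISO_EA, max(ISO_TEMPS_C),
                                            alpha_end = 0.9, t_end = 60))
}

fx_iso_curves <- function(code = "R1", noise_sd = 0, seed_base = 100L) {
  ar <- fx_iso_arrhenius(code)
  lapply(seq_along(ISO_TEMPS_C), function(i) {
    simulate_isothermal(code, ar, ISO_TEMPS_C[i], times = ISO_TIMES,
                        noise_sd = noise_sd,
                        seed = if (noise_sd > 0) seed_base + i else NULL)
  })
}

fx_noniso_curves <- function(code = "R2", method = "ode") {
  ar <- arrhenius_spec(NONISO_EA, NONISO_LNA)
  lapply(NONISO_BETAS, function(b) {
    simulate_nonisothermal(code, ar, beta = b, method = method)
  })
}

# dense alpha grid clipped inside every model's domain
fx_alpha_grid <- function(n = 99) seq(0.01, 0.99, length.out = n)
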