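# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Degree of dissociation by bisection on Ka = alpha^2 c / (1 - alpha).
ostwald_bisect <- function(c_total, ka, tol = 1e-14) {
  f <- function(a) a^2 * c_total / (1 - a) - ka
  lo <- 0; hi <- 1 - 1e-15
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Undissociated acid at fixed pH by bisection on the mass-action balance
# Ka * [HA] = (C_T - [HA]) * [H+]  (charge balance route, no closed form).
hh_bisect <- function(c_total, ph, pka) {
  h <- 10^(-ph); ka <- 10^(-pka)
  f <- function(ha) ka * ha - (c_total - ha) * h
  lo <- 0; hi <- c_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# A minimal single-period truth for round-trip tests.
simple_truth <- function(eta_h = 0.15, eta_a = 0.70, phi = 0.37,
                         eta_m = 0.02, eta_p = 0.6, lactate_share = 0,
                         noise_cv = 0, seed = 1L, day_end = 30,
                         substrate = mixed_sludge_substrate()) {
  synthetic_truth(
    substrate = substrate,
    schedule = reactor_schedule(
      5, data.frame(day_start = 0, day_end = day_end, olr = 14.2, hrt = 5),
      substrate),
    eta_hydrolysis = eta_h, eta_acidogenesis = eta_a, phi_acetate = phi,
    eta_methanogenesis_1st = eta_m, eta_protein = eta_p,
    vfa_mix = c(pr = 0.4, bu = 0.4, iv = 0.2),
    lactate_share = lactate_share, co2_to_ch4_c = 1, f_co2_ferm = 0.05,
    h2_vol_frac = 0.01, noise_cv = noise_cv, seed = seed)
}
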