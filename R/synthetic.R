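# Run code with a fixed RNG seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Mean-one multiplicative lognormal noise at a given coefficient of variation.
.lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Empirical monotone pH map from total standing acid (g/L), calibrated to
# pass near pH 6.1 at sludge-like acid levels (~14 g/L) and pH 3.9 at
# food-waste-like levels (~32 g/L). The pipeline consumes pH only for
# speciation; no mechanistic pH model is attempted.
.ph_from_acids <- function(total_acid_g_l) {
  pmin(pmax(7.6 - 0.115 * total_acid_g_l, 3.5), 7.8)
}

#' Ground truth for a synthetic acid-stage reactor experiment
#'
#' Encodes the stage efficiencies as generative parameters: hydrolysis
#' releases `eta_hydrolysis` of the particulate carbon, acidogenesis
#' converts `eta_acidogenesis` of the dissolved pool (residual DOC + gas
#' carbon) to acids-plus-gas, `phi_acetate` is acetate's share of the
#' lactate-free standing VFA carbon, `eta_methanogenesis_1st` the methane
#' carbon per ingoing TOC and `eta_protein` the fraction of raw protein
#' hydrolyzed. Carbon flow is constructed so that, noise-free, running
#' [stage_report()] on the generated series returns exactly these values.
#'
#' @param substrate A [substrate_characterization()].
#' @param schedule A [reactor_schedule()].
#' @param eta_hydrolysis,eta_acidogenesis,phi_acetate,eta_methanogenesis_1st,eta_protein
#'   Fractions in `[0, 1]`, scalar or one value per schedule period.
#' @param vfa_mix Named shares (codes `pr, bu, iv, ca, hep`) splitting the
#'   non-acetate, non-lactate VFA carbon; must sum to 1.
#' @param lactate_share Fraction of standing acidified carbon held as
#'   lactate.
#' @param co2_to_ch4_c CO2 carbon produced per methane carbon
#'   (methanogenic stoichiometry; 1 = acetoclastic).
#' @param f_co2_ferm Fermentative CO2 carbon as a fraction of acidified
#'   carbon.
#' @param h2_vol_frac H2 share of produced gas volume.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 = noise-free).
#' @param seed Integer RNG seed.
#' @param preset One of `"sludge_co"`, `"sludge_ww"`, `"food_waste_co"`,
#'   `"food_waste_ww"`: parameter sets echoing the four bench reactors
#'   (inoculum from a co-digestion plant or a wastewater-treatment digester,
#'   fed mixed sludge or food waste). A preset fills all arguments not
#'   explicitly supplied.
#' @return A `synthetic_truth` object.
#' @examples
#' synthetic_truth(preset = "sludge_co")
#' @export
synthetic_truth <- function(substrate = NULL, schedule = NULL,
                            eta_hydrolysis = NULL, eta_acidogenesis = NULL,
                            phi_acetate = NULL,
                            eta_methanogenesis_1st = NULL,
                            eta_protein = NULL, vfa_mix = NULL,
                            lactate_share = NULL, co2_to_ch4_c = NULL,
                            f_co2_ferm = NULL, h2_vol_frac = NULL,
                            noise_cv = NULL, seed = NULL, preset = NULL) {
  args <- list(substrate = substrate, schedule = schedule,
               eta_hydrolysis = eta_hydrolysis,
               eta_acidogenesis = eta_acidogenesis,
               phi_acetate = phi_acetate,
               eta_methanogenesis_1st = eta_methanogenesis_1st,
               eta_protein = eta_protein, vfa_mix = vfa_mix,
               lactate_share = lactate_share, co2_to_ch4_c = co2_to_ch4_c,
               f_co2_ferm = f_co2_ferm, h2_vol_frac = h2_vol_frac,
               noise_cv = noise_cv, seed = seed)
  defaults <- if (!is.null(preset)) .truth_preset(preset) else
    list(vfa_mix = c(pr = 0.4, bu = 0.4, iv = 0.2), lactate_share = 0,
         co2_to_ch4_c = 1, f_co2_ferm = 0.05, h2_vol_frac = 0.01,
         noise_cv = 0.05, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  missing <- names(args)[vapply(args, is.null, logical(1))]
  if (length(missing) > 0L) {
    abort(paste0("synthetic_truth needs (directly or via preset): ",
                 paste(missing, collapse = ", ")))
  }
  stopifnot(inherits(args$substrate, "substrate_characterization"),
            inherits(args$schedule, "reactor_schedule"))

  n_per <- nrow(args$schedule$periods)
  for (nm in c("eta_hydrolysis", "eta_acidogenesis", "phi_acetate",
               "eta_methanogenesis_1st", "eta_protein", "lactate_share")) {
    v <- rep_len(args[[nm]], n_per)
    if (any(v < 0 | v > 1)) abort(paste0(nm, " must lie in [0, 1]"))
    args[[nm]] <- v
  }
  if (abs(sum(args$vfa_mix) - 1) > 1e-9) {
    abort("vfa_mix shares must sum to 1")
  }
  if (!all(names(args$vfa_mix) %in% setdiff(names(.vfa_cols),
                                            c("ac", "lac")))) {
    abort("vfa_mix names must be non-acetate, non-lactate acid codes")
  }
  truth <- structure(args, class = "synthetic_truth")
  # fail fast on infeasible carbon flows
  for (i in seq_len(n_per)) .period_flows(truth, i)
  truth
}

.truth_preset <- function(preset) {
  wv <- 5  # L working volume, bench scale
  sludge <- function() reactor_schedule(
    wv, data.frame(day_start = c(0, 50), day_end = c(50, 65),
                   olr = c(14.2, 23.7), hrt = c(5, 3)),
    mixed_sludge_substrate())
  food <- function(day_last) reactor_schedule(
    wv, data.frame(day_start = c(0, 20), day_end = c(20, day_last),
                   olr = c(27, 13.5), hrt = c(5, 10)),
    food_waste_substrate())
  common <- list(co2_to_ch4_c = 1, f_co2_ferm = 0.05, h2_vol_frac = 0.01,
                 noise_cv = 0.05, seed = 1L)
  p <- switch(
    preset,
    sludge_co = list(
      substrate = mixed_sludge_substrate(), schedule = sludge(),
      eta_hydrolysis = c(0.15, 0.15), eta_acidogenesis = c(0.71, 0.61),
      phi_acetate = c(0.37, 0.40), eta_methanogenesis_1st = c(0.02, 0.02),
      eta_protein = c(0.65, 0.57), lactate_share = 0,
      vfa_mix = c(pr = 0.4, bu = 0.4, iv = 0.2)),
    sludge_ww = list(
      substrate = mixed_sludge_substrate(), schedule = sludge(),
      eta_hydrolysis = c(0.15, 0.10), eta_acidogenesis = c(0.66, 0.48),
      phi_acetate = c(0.38, 0.25), eta_methanogenesis_1st = c(0.04, 0.07),
      eta_protein = c(0.53, 0.59), lactate_share = 0,
      vfa_mix = c(pr = 0.4, bu = 0.4, iv = 0.2)),
    food_waste_co = list(
      substrate = food_waste_substrate(), schedule = food(200),
      eta_hydrolysis = c(0.06, 0.07), eta_acidogenesis = c(0.61, 0.56),
      phi_acetate = c(0.40, 0.58), eta_methanogenesis_1st = c(0.01, 0),
      eta_protein = c(0.17, 0.17), lactate_share = 0.3,
      vfa_mix = c(bu = 0.5, pr = 0.2, hep = 0.3)),
    food_waste_ww = list(
      substrate = food_waste_substrate(), schedule = food(65),
      eta_hydrolysis = c(0.01, 0.02), eta_acidogenesis = c(0.38, 0.65),
      phi_acetate = c(0.37, 0.21), eta_methanogenesis_1st = c(0.01, 0),
      eta_protein = c(0.15, 0.15), lactate_share = 0.7,
      vfa_mix = c(bu = 0.5, pr = 0.3, hep = 0.2)),
    abort(paste0("unknown preset: ", preset, " (use sludge_co, sludge_ww, ",
                 "food_waste_co or food_waste_ww)"))
  )
  c(p, common)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic truth> substrate: %s, %d period(s), noise CV %.2f\n",
              x$substrate$name, nrow(x$schedule$periods), x$noise_cv))
  invisible(x)
}

# Noise-free steady-state carbon flows for one period (all mg C/L substrate).
.period_flows <- function(truth, period) {
  s <- truth$substrate
  i <- period
  released <- truth$eta_hydrolysis[i] * (s$toc_tot - s$doc_in)
  pool <- s$doc_in + released
  ch4_c <- truth$eta_methanogenesis_1st[i] * s$toc_tot
  acidified <- truth$eta_acidogenesis[i] * pool
  co2_c <- truth$co2_to_ch4_c * ch4_c + truth$f_co2_ferm * acidified
  tc_gases <- ch4_c + co2_c
  doc_res <- pool - tc_gases
  standing <- acidified - tc_gases
  if (doc_res < 0) {
    abort(sprintf("infeasible period %d: gas carbon exceeds dissolved pool",
                  i))
  }
  if (standing < 0) {
    abort(sprintf(
      "infeasible period %d: gas carbon exceeds acidified carbon", i))
  }
  lac_c <- truth$lactate_share[i] * standing
  vfa_c <- standing - lac_c
  ac_c <- truth$phi_acetate[i] * vfa_c
  other_c <- (1 - truth$phi_acetate[i]) * vfa_c * truth$vfa_mix
  reg <- acid_registry()
  conc <- c(ac = ac_c / (carbon_fraction("acetic", reg) * 1000),
            vapply(names(other_c), function(cc) {
              other_c[[cc]] / (reg$carbon_fraction[
                match(.vfa_cols[[cc]], reg$name)] * 1000)
            }, numeric(1)),
            lac = if (lac_c > 0)
              lac_c / (carbon_fraction("lactic", reg) * 1000) else 0)
  list(released = released, pool = pool, ch4_c = ch4_c, co2_c = co2_c,
       tc_gases = tc_gases, doc_res = doc_res, standing = standing,
       conc_g_l = conc)
}

#' Generate a synthetic reactor time series
#'
#' Produces daily liquid and gas observation tables in the tidy dialect
#' consumed by [stage_report()] and [read_timeseries()]. Noise-free
#' (`noise_cv = 0`), [stage_report()] recovers the truth's efficiencies
#' exactly; noisy mode multiplies each observable by mean-one lognormal
#' noise per day, reproducibly for a fixed seed. pH is emitted through a
#' fixed empirical monotone map from the total standing acid concentration.
#'
#' @param truth A [synthetic_truth()].
#' @param n_days Days to simulate (day 1 .. n_days; capped at the schedule's
#'   last day).
#' @param noise_cv,seed Override the truth's noise level / seed.
#' @return List with tibbles `liquid` and `gas`.
#' @examples
#' obs <- generate_series(synthetic_truth(preset = "sludge_co"), n_days = 30)
#' head(obs$liquid)
#' @export
generate_series <- function(truth, n_days = NULL, noise_cv = NULL,
                            seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  noise_cv <- noise_cv %||% truth$noise_cv
  seed <- seed %||% truth$seed
  periods <- truth$schedule$periods
  n_days <- min(n_days %||% max(periods$day_end), max(periods$day_end))
  days <- seq_len(n_days)
  which_period <- findInterval(days, periods$day_start,
                               rightmost.closed = FALSE)
  which_period[days >= periods$day_end[nrow(periods)]] <- nrow(periods)
  s <- truth$substrate

  .with_seed(seed, {
    liq_rows <- list()
    gas_rows <- list()
    for (d in seq_along(days)) {
      i <- which_period[d]
      fl <- .period_flows(truth, i)
      feed <- truth$schedule$working_volume / periods$hrt[i]
      conc <- fl$conc_g_l * .lnoise(length(fl$conc_g_l), noise_cv)
      nh4_out <- s$kjeldahl_n -
        (1 - truth$eta_protein[i]) * (s$kjeldahl_n - s$nh4_n)
      mol_ch4 <- fl$ch4_c / 1000 / .const$M_C * feed
      mol_co2 <- fl$co2_c / 1000 / .const$M_C * feed
      vol_c <- (mol_ch4 + mol_co2) * .const$molar_vol
      vol_tot <- vol_c / (1 - truth$h2_vol_frac)
      liq_rows[[d]] <- tibble::tibble(
        day = days[d],
        ph = .ph_from_acids(sum(conc)),
        ac = conc[["ac"]],
        pr = conc["pr"] %|0|% NA_real_, ib = NA_real_,
        bu = conc["bu"] %|0|% NA_real_, iv = conc["iv"] %|0|% NA_real_,
        va = NA_real_, ca = conc["ca"] %|0|% NA_real_,
        hep = conc["hep"] %|0|% NA_real_,
        lac = conc[["lac"]],
        doc_res = fl$doc_res * .lnoise(1, noise_cv),
        kjn = s$kjeldahl_n * .lnoise(1, noise_cv),
        nh4n = nh4_out * .lnoise(1, noise_cv)
      )
      gas_rows[[d]] <- tibble::tibble(
        day = days[d],
        volume_norm = vol_tot * .lnoise(1, noise_cv),
        ch4_frac = if (vol_tot > 0) mol_ch4 * .const$molar_vol / vol_tot
          else 0,
        co2_frac = if (vol_tot > 0) mol_co2 * .const$molar_vol / vol_tot
          else 0,
        h2_frac = if (vol_tot > 0) truth$h2_vol_frac else 0
      )
    }
    list(liquid = dplyr::bind_rows(liq_rows), gas = dplyr::bind_rows(gas_rows))
  })
}

# named-subscript-or-NA helper for optional vfa components
`%|0|%` <- function(x, default) {
  if (length(x) == 0L || is.null(names(x)) || anyNA(names(x))) default
  else unname(x)
}

#' Generate a synthetic BMP bottle set
#'
#' Cumulative methane curves follow first-order accumulation,
#' `B(t) = BMP * VS * (1 - exp(-k t))`, on top of the inoculum's endogenous
#' (blank) production; blanks are generated consistently from the same
#' endogenous parameters. Noise multiplies the daily increments (mean-one
#' lognormal), preserving monotonicity.
#'
#' @param true_bmp Ultimate methane potential, mL CH4 per g substrate VS.
#' @param k First-order rate constant, 1/d.
#' @param n_bottles Sample bottles (triplicate by default).
#' @param blank_level Endogenous ultimate methane, mL per g inoculum VS.
#' @param noise_cv Coefficient of variation of increment noise.
#' @param seed Integer RNG seed.
#' @param substrate_vs_g Substrate VS per bottle, g (assay loading of
#'   3 g VS/L in 0.4 L at a 3:1 inoculum:substrate VS ratio gives 0.3 g).
#' @param substrate_mass_g Wet substrate mass per bottle, g; default assumes
#'   a food-waste-like VS content of 13.5% of wet weight.
#' @param inoculum_vs_g Inoculum VS per bottle, g.
#' @param n_blanks Blank bottles.
#' @param blank_k First-order rate of the endogenous production, 1/d.
#' @param days Sampling days.
#' @return A [bmp_set()].
#' @examples
#' set <- generate_bmp(true_bmp = 370, k = 0.3, seed = 7)
#' bmp_per_gram(set, basis = "vs")$mean
#' @export
generate_bmp <- function(true_bmp, k = 0.3, n_bottles = 3, blank_level = 20,
                         noise_cv = 0.05, seed = 1L, substrate_vs_g = 0.3,
                         substrate_mass_g = substrate_vs_g / 0.135,
                         inoculum_vs_g = 0.9, n_blanks = 3, blank_k = 0.15,
                         days = 0:15) {
  if (k <= 0) abort("first-order rate k must be positive")
  if (true_bmp < 0) abort("true_bmp must be non-negative")
  firstorder <- function(amp, rate) amp * (1 - exp(-rate * days))
  noisy <- function(curve) {
    inc <- diff(c(0, curve))
    cumsum(inc * .lnoise(length(inc), noise_cv))
  }
  .with_seed(seed, {
    bottles <- list()
    curves <- list()
    blank_per_g <- firstorder(blank_level, blank_k)
    for (b in seq_len(n_bottles)) {
      lab <- sprintf("sample_%d", b)
      bottles[[lab]] <- tibble::tibble(
        label = lab, role = "sample", substrate_mass_g = substrate_mass_g,
        substrate_vs_g = substrate_vs_g, inoculum_vs_g = inoculum_vs_g)
      curves[[lab]] <- tibble::tibble(
        label = lab, day = days,
        ml_ch4 = noisy(firstorder(true_bmp * substrate_vs_g, k) +
                         inoculum_vs_g * blank_per_g))
    }
    for (b in seq_len(n_blanks)) {
      lab <- sprintf("blank_%d", b)
      bottles[[lab]] <- tibble::tibble(
        label = lab, role = "blank", substrate_mass_g = 0,
        substrate_vs_g = 0, inoculum_vs_g = inoculum_vs_g)
      curves[[lab]] <- tibble::tibble(
        label = lab, day = days,
        ml_ch4 = noisy(inoculum_vs_g * blank_per_g))
    }
    bmp_set(dplyr::bind_rows(bottles), dplyr::bind_rows(curves))
  })
}

#' Generate a synthetic dilution-inhibition series
#'
#' Post-incubation acetate versus hydrolysate volume fraction. In the
#' no-toxicity regime the response is linear, `y = base * fraction +
#' production_offset`; the toxicity regime adds a concave bump,
#' `toxicity_amp * fraction * (1 - fraction)`, the signature of extra
#' production unlocked by dilution, for power tests of the linearity check.
#'
#' @param base_acetate Undiluted acetate, g/L.
#' @param fractions Hydrolysate volume fractions; default is the five-level
#'   study design (10:90 .. 0:100 tapwater:hydrolysate).
#' @param production_offset Fraction-independent production, g/L.
#' @param toxicity_amp Amplitude of the concave toxicity-release bump, g/L
#'   (0 = linear regime).
#' @param noise_sd Additive Gaussian measurement noise, g/L (0.15 g/L
#'   reproduces the near-perfect linearity, R^2 ~ 0.9997, typical of such
#'   assays).
#' @param n_replicates Readings per fraction.
#' @param seed Integer RNG seed.
#' @return Tibble `fraction`, `replicate`, `acetate_after` for
#'   [dilution_linear_fit()].
#' @examples
#' dilution_linear_fit(generate_dilution(20, noise_sd = 0, seed = 1))$slope
#' @export
generate_dilution <- function(base_acetate,
                              fractions = c(0.10, 0.50, 0.75, 0.90, 1.00),
                              production_offset = 0, toxicity_amp = 0,
                              noise_sd = 0.15, n_replicates = 3, seed = 1L) {
  if (any(fractions < 0 | fractions > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  if (is.unsorted(fractions, strictly = TRUE)) {
    abort("fractions must be strictly increasing")
  }
  .with_seed(seed, {
    grid <- tidyr::expand_grid(fraction = fractions,
                               replicate = seq_len(n_replicates))
    y <- base_acetate * grid$fraction + production_offset +
      toxicity_amp * grid$fraction * (1 - grid$fraction) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    grid$acetate_after <- pmax(y, 0)
    grid
  })
}
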