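#' Undissociated weak acid via Henderson-Hasselbalch
#'
#' At a measured pH, the protonated (membrane-permeant, potentially toxic)
#' fraction of a monoprotic weak acid is `1 / (1 + 10^(pH - pKa))`.
#' Conservation holds exactly: undissociated + dissociated = total.
#'
#' @param c_total Total acid concentration (any concentration unit; the
#'   result is in the same unit).
#' @param ph Solution pH.
#' @param pka Acid pKa. pKa values are parameters, not constants: shipped
#'   registry values are ~25 degree C literature values and reactors often
#'   run warmer; supply a temperature-corrected value if you have one.
#' @return List with `undissociated`, `dissociated` and `alpha` (fraction
#'   dissociated).
#' @examples
#' undissociated_hh(20, ph = 3.9, pka = 4.756)
#' @export
undissociated_hh <- function(c_total, ph, pka) {
  if (any(c_total < 0)) abort("c_total must be non-negative")
  ratio <- 10^(ph - pka)          # [A-]/[HA]
  und <- c_total / (1 + ratio)
  list(undissociated = und, dissociated = c_total - und,
       alpha = ratio / (1 + ratio))
}

#' Undissociated weak acid via Ostwald's dilution law
#'
#' Solves `Ka = alpha^2 c / (1 - alpha)` for the degree of dissociation
#' alpha of a weak acid alone in water (no pH measurement needed), using the
#' positive root of the quadratic `c alpha^2 + Ka alpha - Ka = 0`. The
#' implied pH is `-log10(alpha c)`.
#'
#' @param c_total Total acid concentration, mol/L.
#' @param ka Acid dissociation constant (e.g. `10^-4.756` for acetic acid).
#' @return List with `alpha` (fraction dissociated), `undissociated_mol_l`,
#'   and `implied_ph`.
#' @examples
#' undissociated_ostwald(0.333, ka = 10^-4.756)
#' @export
undissociated_ostwald <- function(c_total, ka) {
  if (any(c_total <= 0) || any(ka <= 0)) {
    abort("c_total and ka must be positive")
  }
  alpha <- (-ka + sqrt(ka^2 + 4 * c_total * ka)) / (2 * c_total)
  if (any(alpha <= 0) || any(alpha >= 1)) {
    abort("no dissociation root in (0, 1); check inputs")
  }
  list(alpha = alpha,
       undissociated_mol_l = (1 - alpha) * c_total,
       implied_ph = -log10(alpha * c_total))
}

#' Speciate an acid by one or both routes
#'
#' Convenience wrapper reporting grams-per-litre undissociated acid by the
#' Henderson-Hasselbalch route (requires a measured pH) and/or the Ostwald
#' dilution-law route (acid alone in water; reports the pH it implies). The
#' two bracket the truth for real hydrolysates, whose pH is set by the full
#' acid mixture: results print both so no route is silently preferred.
#'
#' @param conc_g_l Total acid concentration, g/L.
#' @param species Registry species name.
#' @param ph Measured pH (needed for `method = "hh"` or `"both"`).
#' @param pka Override pKa; defaults to the registry value.
#' @param method `"hh"`, `"ostwald"` or `"both"`.
#' @param registry Acid registry.
#' @return Tibble with one row per route: `method`, `undissociated_g_l`,
#'   `alpha`, `ph` (measured or implied).
#' @examples
#' speciate(20, "acetic", ph = 3.9)
#' @export
speciate <- function(conc_g_l, species, ph = NULL, pka = NULL,
                     method = c("both", "hh", "ostwald"),
                     registry = acid_registry()) {
  method <- match.arg(method)
  sp <- acid_species(species, registry)
  pka <- pka %||% sp$pka
  if (is.na(pka)) abort(paste0("species '", species, "' has no pKa"))
  out <- list()
  if (method %in% c("hh", "both")) {
    if (is.null(ph)) abort("Henderson-Hasselbalch route needs a measured pH")
    hh <- undissociated_hh(conc_g_l, ph, pka)
    out <- c(out, list(tibble::tibble(
      method = "henderson-hasselbalch",
      undissociated_g_l = hh$undissociated, alpha = hh$alpha, ph = ph)))
  }
  if (method %in% c("ostwald", "both")) {
    ost <- undissociated_ostwald(conc_g_l / sp$molar_mass, 10^(-pka))
    out <- c(out, list(tibble::tibble(
      method = "ostwald",
      undissociated_g_l = ost$undissociated_mol_l * sp$molar_mass,
      alpha = ost$alpha, ph = ost$implied_ph)))
  }
  dplyr::bind_rows(out)
}

#' Mean with Student-t confidence half-width
#'
#' `mean +/- t(1 - alpha/2, n-1) * sd / sqrt(n)`, the two-sided confidence
#' interval used for all replicate summaries in the package.
#'
#' @param values Numeric vector, length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List with `mean`, `half_width`, `n`.
#' @examples
#' confidence_interval(c(1, 2, 3))
#' @export
confidence_interval <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) abort("confidence_interval needs at least 2 values")
  list(mean = mean(values),
       half_width = qt(1 - alpha / 2, n - 1L) * sd(values) / sqrt(n),
       n = n)
}

#' Linear fit of a dilution-inhibition series
#'
#' Ordinary least squares of post-incubation acetate on the hydrolysate
#' volume fraction. A strictly linear response (production proportional to
#' the amount of hydrolysate) means dilution did not unlock extra
#' production, i.e. the undissociated acid level was not limiting; positive
#' residual curvature (diluted bottles above the line) is the signature of
#' toxicity release. Curvature is assessed by the t-test on the quadratic
#' coefficient of a second-order fit.
#'
#' @param series A tibble with columns `fraction` (hydrolysate volume
#'   fraction, 0-1) and `acetate_after` (g/L), e.g. from
#'   [generate_dilution()]; replicate rows per fraction are allowed.
#' @param alpha Significance level for the curvature test.
#' @return List with `slope`, `intercept`, `r_squared` (`NA` with a
#'   `degenerate` flag when the response has zero variance), `curvature_p`,
#'   `toxicity_release` (logical: concave curvature detected) and the `lm`
#'   fits.
#' @examples
#' s <- generate_dilution(base_acetate = 20, noise_sd = 0, seed = 1)
#' dilution_linear_fit(s)
#' @export
dilution_linear_fit <- function(series, alpha = 0.05) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("fraction", "acetate_after") %in% names(series)))
  if (length(unique(series$fraction)) < 3L) {
    abort("dilution fit needs >= 3 distinct hydrolysate fractions")
  }
  if (sd(series$fraction) == 0) abort("zero variance in fractions")
  fit <- lm(acetate_after ~ fraction, data = series)
  ss_tot <- sum((series$acetate_after - mean(series$acetate_after))^2)
  degenerate <- ss_tot <= .Machine$double.eps * nrow(series)
  # exact (noise-free) fits are a legitimate input here; silence the
  # "essentially perfect fit" advisory from summary.lm
  r2 <- if (degenerate) NA_real_ else
    suppressWarnings(summary(fit)$r.squared)

  fit2 <- lm(acetate_after ~ fraction + I(fraction^2), data = series)
  co2 <- suppressWarnings(summary(fit2)$coefficients)
  curv_p <- if ("I(fraction^2)" %in% rownames(co2))
    co2["I(fraction^2)", "Pr(>|t|)"] else NA_real_
  curv_est <- if ("I(fraction^2)" %in% rownames(co2))
    co2["I(fraction^2)", "Estimate"] else NA_real_

  list(slope = unname(coef(fit)["fraction"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       r_squared = r2, degenerate = degenerate,
       curvature = curv_est, curvature_p = curv_p,
       toxicity_release = isTRUE(!is.na(curv_p) && curv_p < alpha &&
                                   curv_est < 0),
       fit_linear = fit, fit_quadratic = fit2)
}
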