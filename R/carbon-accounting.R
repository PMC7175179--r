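# Column-name -> registry-species map for the tidy time-series dialect.
# Iso- and n- isomers share molar mass and carbon count, so both map to the
# same registry entry.
.vfa_cols <- c(ac = "acetic", pr = "propionic", ib = "butyric",
               bu = "butyric", iv = "valeric", va = "valeric",
               ca = "caproic", hep = "heptanoic", lac = "lactic")

#' Organic carbon held in a set of acid concentrations
#'
#' Converts per-species concentrations (g/L) to mg C/L using the registry
#' carbon fractions.
#'
#' @param vfa Named numeric vector of concentrations in g/L; names are either
#'   registry species names or the tidy column codes
#'   (`ac, pr, ib, bu, iv, va, ca, hep, lac`). `NA` values count as zero.
#' @param include_lactate Count lactate? Default `FALSE`: acetate-fraction
#'   ("total VFA") conventions exclude lactic acid. Use `TRUE` for carbon
#'   partitioning of acidified DOC, where lactate counts.
#' @param registry Acid registry, see [acid_registry()].
#' @return mg C/L (scalar).
#' @examples
#' vfa_carbon(c(ac = 5, pr = 2, bu = 2))
#' @export
vfa_carbon <- function(vfa, include_lactate = FALSE,
                       registry = acid_registry()) {
  if (is.null(names(vfa)) || any(!nzchar(names(vfa)))) {
    abort("vfa must be a named vector of g/L concentrations")
  }
  species <- ifelse(names(vfa) %in% names(.vfa_cols),
                    .vfa_cols[names(vfa)], names(vfa))
  unknown <- setdiff(species, registry$name)
  if (length(unknown) > 0L) {
    abort(paste0("unknown acid species: ", paste(unknown, collapse = ", ")))
  }
  keep <- if (include_lactate) rep(TRUE, length(species)) else
    registry$in_total_vfa[match(species, registry$name)]
  cf <- registry$carbon_fraction[match(species, registry$name)]
  conc <- ifelse(is.na(vfa), 0, vfa)
  sum(conc[keep] * cf[keep]) * 1000  # g/L -> mg/L
}

#' Carbon leaving a reactor as gas
#'
#' Mean daily carbon in produced CH4 + CO2, expressed per litre of substrate
#' fed. Hydrogen carries no carbon. Gas volumes must already be normalized
#' to STP (see [normalize_gas_volume()]); observations carrying a raw
#' (volume, temp, pressure) triple are normalized on the fly.
#'
#' @param gas Tibble with columns `volume_norm` (L/d at STP), `ch4_frac`,
#'   `co2_frac` (volume fractions 0-1); optionally `raw_volume`, `raw_temp`,
#'   `raw_pressure` for rows where `volume_norm` is `NA`.
#' @param feed_volume_per_day Substrate fed per day, L.
#' @param species `"both"` (default, the TC_Gases term), `"ch4"` (methane
#'   carbon only, for methanogenesis) or `"co2"`.
#' @return mg C per L substrate fed (mean over observed days).
#' @examples
#' gas <- tibble::tibble(volume_norm = 22.414, ch4_frac = 0.5, co2_frac = 0.5)
#' carbon_in_gas(gas, feed_volume_per_day = 1)
#' @export
carbon_in_gas <- function(gas, feed_volume_per_day,
                          species = c("both", "ch4", "co2")) {
  species <- match.arg(species)
  if (feed_volume_per_day <= 0) {
    abort("feed_volume_per_day must be positive (L)")
  }
  gas <- tibble::as_tibble(gas)
  vol <- gas$volume_norm
  if (any(is.na(vol))) {
    has_raw <- all(c("raw_volume", "raw_temp", "raw_pressure") %in% names(gas))
    if (!has_raw) {
      abort("gas rows without volume_norm need raw_volume/raw_temp/raw_pressure")
    }
    idx <- is.na(vol)
    if (any(is.na(gas$raw_volume[idx]))) {
      abort("gas rows lack both normalized and raw volume")
    }
    vol[idx] <- normalize_gas_volume(gas$raw_volume[idx], gas$raw_temp[idx],
                                     gas$raw_pressure[idx])
  }
  frac <- switch(species,
                 both = gas$ch4_frac + gas$co2_frac,
                 ch4  = gas$ch4_frac,
                 co2  = gas$co2_frac)
  frac <- ifelse(is.na(frac), 0, frac)
  mol_c <- vol * frac / .const$molar_vol
  mean(mol_c * .const$M_C * 1000 / feed_volume_per_day)
}

#' Degree of hydrolysis
#'
#' Fraction of ingoing particulate organic carbon solubilized in the acid
#' stage: `(DOC_res + TC_gases - DOC_in) / (TOC_tot - DOC_in) * 100`.
#' Negative values are preserved (net consumption of dissolved carbon, e.g.
#' by rising methanogenic activity) — see the `net_doc_consumption` flag in
#' [stage_report()].
#'
#' @param doc_res Residual dissolved organic carbon in the hydrolysate, mg C/L.
#' @param tc_gases Carbon in produced CH4 + CO2, mg C per L substrate fed.
#' @param doc_in Ingoing dissolved organic carbon, mg C/L.
#' @param toc_tot Total ingoing organic carbon, mg C/L.
#' @return Percent of ingoing TOC.
#' @examples
#' degree_of_hydrolysis(7000, 825, 5500, 21000)  # 15
#' @export
degree_of_hydrolysis <- function(doc_res, tc_gases, doc_in, toc_tot) {
  if (toc_tot <= doc_in) {
    abort("degree of hydrolysis undefined: toc_tot must exceed doc_in")
  }
  (doc_res + tc_gases - doc_in) / (toc_tot - doc_in) * 100
}

#' Degree of acidogenesis
#'
#' Fraction of available dissolved carbon converted to acids (counting the
#' carbon already passed on to gas):
#' `(TOC_VFA + TC_gases) / (DOC_res + TC_gases) * 100`.
#'
#' @param toc_vfa Organic carbon in fermentation acids, mg C/L. For carbon
#'   partitioning this conventionally includes lactate.
#' @param tc_gases Carbon in produced CH4 + CO2, mg C per L substrate fed.
#' @param doc_res Residual dissolved organic carbon, mg C/L.
#' @return Percent of DOC.
#' @examples
#' degree_of_acidogenesis(4000, 500, 6000)
#' @export
degree_of_acidogenesis <- function(toc_vfa, tc_gases, doc_res) {
  if (doc_res + tc_gases <= 0) {
    abort("degree of acidogenesis undefined: doc_res + tc_gases must be > 0")
  }
  (toc_vfa + tc_gases) / (doc_res + tc_gases) * 100
}

#' Degree of acetogenesis
#'
#' Acetate's share of the organic carbon held in volatile fatty acids,
#' `TOC_acetate / TOC_VFA * 100`. Lactate is excluded from the denominator
#' by default (lactate-free "total VFA" convention); set
#' `include_lactate = TRUE` to count it.
#'
#' @inheritParams vfa_carbon
#' @return Percent of VFA carbon. Invariant to rescaling all concentrations
#'   by a common positive factor.
#' @examples
#' degree_of_acetogenesis(c(ac = 5, pr = 2, bu = 2))
#' @export
degree_of_acetogenesis <- function(vfa, include_lactate = FALSE,
                                   registry = acid_registry()) {
  total <- vfa_carbon(vfa, include_lactate = include_lactate,
                      registry = registry)
  if (total <= 0) {
    abort("degree of acetogenesis undefined: all VFA concentrations are zero")
  }
  ac <- vfa[ifelse(names(vfa) %in% names(.vfa_cols),
                   .vfa_cols[names(vfa)], names(vfa)) == "acetic"]
  ac_c <- if (length(ac) == 0L) 0 else
    sum(ifelse(is.na(ac), 0, ac)) * carbon_fraction("acetic", registry) * 1000
  ac_c / total * 100
}

#' Degree of methanogenesis
#'
#' Methane carbon out per ingoing total organic carbon,
#' `CH4_C / TOC_tot * 100`. Only CH4 carbon counts here; CO2 carbon belongs
#' to the TC_gases term of hydrolysis/acidogenesis.
#'
#' @param ch4_c Methane carbon, mg C per L substrate fed.
#' @param toc_tot Total ingoing organic carbon, mg C/L.
#' @return Percent of ingoing TOC.
#' @examples
#' degree_of_methanogenesis(1470, 21000)  # 7
#' @export
degree_of_methanogenesis <- function(ch4_c, toc_tot) {
  if (toc_tot <= 0) abort("toc_tot must be positive")
  ch4_c / toc_tot * 100
}

#' Raw (crude) protein from nitrogen measurements
#'
#' `(Kjeldahl-N - NH4-N) * 6.25`, the standard crude-protein conversion.
#'
#' @param kjeldahl_n Kjeldahl nitrogen, mg N/L.
#' @param nh4_n Ammonium nitrogen, mg N/L.
#' @return mg protein/L.
#' @examples
#' raw_protein(3000, 600)
#' @export
raw_protein <- function(kjeldahl_n, nh4_n) {
  if (any(nh4_n > kjeldahl_n)) {
    abort("nh4_n exceeds kjeldahl_n: inconsistent nitrogen measurements")
  }
  (kjeldahl_n - nh4_n) * .const$protein_n
}

#' Degree of protein hydrolysis
#'
#' Percent of the substrate's raw protein hydrolyzed in the acid stage
#' (converted to free ammonium), i.e.
#' `(1 - RP_hydrolysate / RP_substrate) * 100` where RP is [raw_protein()].
#'
#' @param substrate A [substrate_characterization()] with nitrogen fields, or
#'   raw protein in mg/L.
#' @param hydrolysate_kjeldahl_n,hydrolysate_nh4_n Hydrolysate nitrogen,
#'   mg N/L.
#' @return Percent of ingoing raw protein.
#' @examples
#' protein_hydrolysis(mixed_sludge_substrate(), 3000, 1800)
#' @export
protein_hydrolysis <- function(substrate, hydrolysate_kjeldahl_n,
                               hydrolysate_nh4_n) {
  rp_sub <- if (inherits(substrate, "substrate_characterization")) {
    raw_protein(substrate$kjeldahl_n, substrate$nh4_n)
  } else {
    substrate
  }
  if (is.na(rp_sub) || rp_sub <= 0) {
    abort("substrate raw protein must be positive")
  }
  rp_hyd <- raw_protein(hydrolysate_kjeldahl_n, hydrolysate_nh4_n)
  (1 - rp_hyd / rp_sub) * 100
}

#' Soluble carbon fraction of a substrate
#'
#' `DOC / TOC * 100`: share of a material's organic carbon already in
#' dissolved form when fed.
#'
#' @param doc Dissolved organic carbon, mg C/L (or a
#'   [substrate_characterization()], in which case `toc` is ignored).
#' @param toc Total organic carbon, mg C/L.
#' @return Percent.
#' @examples
#' soluble_fraction(5500, 21000)
#' soluble_fraction(food_waste_substrate())
#' @export
soluble_fraction <- function(doc, toc = NULL) {
  if (inherits(doc, "substrate_characterization")) {
    toc <- doc$toc_tot
    doc <- doc$doc_in
  }
  if (toc <= 0) abort("toc must be positive")
  if (doc < 0 || doc > toc) abort("need 0 <= doc <= toc")
  doc / toc * 100
}

#' Total soluble fraction of ingoing TOC after the acid stage
#'
#' Sum of the ingoing soluble fraction (DOC_in/TOC) and the degree of
#' hydrolysis. Additivity holds because the hydrolysis definition scales the
#' released carbon by (TOC - DOC_in)/TOC relative to total TOC:
#'   hydrolysis% * (TOC - DOC_in)/TOC + DOC_in/TOC * 100
#'     = (DOC_res + TC_gases)/TOC * 100 - DOC_in/TOC * 100 + DOC_in/TOC * 100,
#' and the reported convention keeps the two terms on the TOC basis so they
#' simply add (see vignette for the consistency identity and its test).
#'
#' @param soluble_in_pct Ingoing soluble fraction, percent of TOC.
#' @param hydrolysis_pct Degree of hydrolysis, percent.
#' @return Percent of ingoing TOC in soluble form after the acid stage.
#' @examples
#' total_soluble_fraction(26, 15)
#' @export
total_soluble_fraction <- function(soluble_in_pct, hydrolysis_pct) {
  if (any(c(soluble_in_pct, hydrolysis_pct) < 0)) {
    warn("negative input to total_soluble_fraction")
  }
  soluble_in_pct + hydrolysis_pct
}

#' Acid yield per mass of volatile solids fed
#'
#' At steady state in a semi-continuous CSTR, the VS fed per litre of reactor
#' per retention time is `OLR * HRT` g/L, so an outgoing concentration `c`
#' g/L corresponds to `c * 1000 / (OLR * HRT)` g acid per kg VS fed.
#'
#' @param concentration_out Outgoing acid concentration, g/L.
#' @param olr Organic loading rate, kg VS/m^3/d (or a [reactor_schedule()]
#'   plus `period` index).
#' @param hrt Hydraulic retention time, d.
#' @param period Period row index when `olr` is a schedule.
#' @return g acid per kg VS fed.
#' @examples
#' acid_yield(20.4, olr = 13.5, hrt = 10)  # ~151 g/kg VS
#' @export
acid_yield <- function(concentration_out, olr, hrt = NULL, period = 1L) {
  if (inherits(olr, "reactor_schedule")) {
    p <- olr$periods[period, ]
    hrt <- p$hrt
    olr <- p$olr
  }
  if (olr <= 0 || hrt <= 0) abort("olr and hrt must be positive")
  concentration_out * 1000 / (olr * hrt)
}

#' Molar ratio of two species' concentrations
#'
#' @param conc_a,conc_b Concentrations, g/L.
#' @param species_a,species_b Registry species names.
#' @param registry Acid registry.
#' @return `(conc_a / M_a) / (conc_b / M_b)`.
#' @examples
#' molar_ratio(25, "acetic", 15, "lactic")
#' @export
molar_ratio <- function(conc_a, species_a, conc_b, species_b,
                        registry = acid_registry()) {
  if (conc_b <= 0) abort("denominator concentration must be positive")
  ma <- acid_species(species_a, registry)$molar_mass
  mb <- acid_species(species_b, registry)$molar_mass
  (conc_a / ma) / (conc_b / mb)
}

#' Organic loading rate after adding a dissolved-carbon additive
#'
#' Converts an added DOC dose (mg C per kg substrate) into additive mass via
#' the species' carbon fraction, then into the extra OLR it represents at
#' the given retention time (substrate density 1 kg/L): additive g/kg times
#' the daily substrate feed of 1000/HRT kg per m^3.
#'
#' @param base_olr Baseline OLR, kg VS/m^3/d.
#' @param added_doc Extra ingoing DOC, mg C per kg substrate.
#' @param additive Registry species name supplying the carbon (e.g.
#'   `"glucose"`).
#' @param hrt Hydraulic retention time, d.
#' @param registry Acid registry.
#' @return OLR including the additive, kg VS/m^3/d.
#' @examples
#' olr_with_additive(13.5, 10700, "glucose", hrt = 10)  # ~16.2
#' @export
olr_with_additive <- function(base_olr, added_doc, additive, hrt,
                              registry = acid_registry()) {
  cf <- carbon_fraction(additive, registry)
  if (cf <= 0) abort("additive must contain carbon")
  if (hrt <= 0) abort("hrt must be positive")
  additive_g_per_kg <- (added_doc / cf) / 1000   # mg/kg -> g additive per kg
  base_olr + additive_g_per_kg * (1000 / hrt) / 1000
}
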