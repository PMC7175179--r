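#' Substrate characterization
#'
#' Carbon, solids and nitrogen composition of a feed material. All carbon
#' bookkeeping in the package is per litre of substrate fed, assuming a
#' density of 1.0 kg/L unless overridden, so per-kg and per-L bases coincide
#' by default.
#'
#' @param name Substrate label.
#' @param ts_fraction Total solids as a fraction of wet weight (0-1).
#' @param vs_fraction_of_ts Volatile solids as a fraction of TS (0-1).
#' @param doc_in Dissolved organic carbon, mg C/L.
#' @param toc_tot Total organic carbon, mg C/L.
#' @param kjeldahl_n Kjeldahl nitrogen, mg N/L (optional).
#' @param nh4_n Ammonium nitrogen, mg N/L (optional).
#' @param density Substrate density, kg/L.
#' @return A `substrate_characterization` object (list).
#' @examples
#' food_waste_substrate()
#' mixed_sludge_substrate()
#' @export
substrate_characterization <- function(name, ts_fraction, vs_fraction_of_ts,
                                       doc_in, toc_tot,
                                       kjeldahl_n = NA_real_,
                                       nh4_n = NA_real_,
                                       density = 1.0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (ts_fraction < 0 || ts_fraction > 1 ||
      vs_fraction_of_ts < 0 || vs_fraction_of_ts > 1) {
    abort("ts_fraction and vs_fraction_of_ts must be fractions in [0, 1]")
  }
  if (doc_in < 0 || toc_tot < doc_in) {
    abort("need 0 <= doc_in <= toc_tot (mg C/L)")
  }
  if (!is.na(kjeldahl_n) && !is.na(nh4_n) &&
      (nh4_n < 0 || nh4_n > kjeldahl_n)) {
    abort("need 0 <= nh4_n <= kjeldahl_n (mg N/L)")
  }
  if (density <= 0) abort("density must be positive (kg/L)")
  structure(
    list(name = name, ts_fraction = ts_fraction,
         vs_fraction_of_ts = vs_fraction_of_ts, doc_in = doc_in,
         toc_tot = toc_tot, kjeldahl_n = kjeldahl_n, nh4_n = nh4_n,
         density = density),
    class = "substrate_characterization"
  )
}

#' @export
print.substrate_characterization <- function(x, ...) {
  cat(sprintf(
    "<substrate> %s: TS %.1f%%, VS %.0f%% of TS, DOC %.0f / TOC %.0f mg C/L\n",
    x$name, 100 * x$ts_fraction, 100 * x$vs_fraction_of_ts,
    x$doc_in, x$toc_tot))
  invisible(x)
}

#' Study substrates
#'
#' Convenience constructors for the two bench-study feed materials: a
#' source-separated food-waste slurry and a dewatered mixed (primary +
#' secondary) sewage sludge. Nitrogen values default to field-plausible
#' levels for these materials and can be overridden.
#'
#' @param kjeldahl_n,nh4_n mg N/L.
#' @return A [substrate_characterization()] object.
#' @export
food_waste_substrate <- function(kjeldahl_n = 4500, nh4_n = 150) {
  substrate_characterization("food waste", ts_fraction = 0.147,
                             vs_fraction_of_ts = 0.92, doc_in = 24900,
                             toc_tot = 39000, kjeldahl_n = kjeldahl_n,
                             nh4_n = nh4_n)
}

#' @rdname food_waste_substrate
#' @export
mixed_sludge_substrate <- function(kjeldahl_n = 3000, nh4_n = 600) {
  substrate_characterization("mixed sludge", ts_fraction = 0.088,
                             vs_fraction_of_ts = 0.81, doc_in = 5500,
                             toc_tot = 21000, kjeldahl_n = kjeldahl_n,
                             nh4_n = nh4_n)
}

#' Reactor operating schedule
#'
#' Working volume plus contiguous operating periods, each with an organic
#' loading rate (OLR, kg VS/m^3/d) and hydraulic retention time (HRT, d).
#' Daily feed volume within a period is `working_volume / hrt`.
#'
#' @param working_volume Reactor working volume, L.
#' @param periods Data frame with columns `day_start`, `day_end`, `olr`,
#'   `hrt`; periods must be contiguous and non-overlapping.
#' @param substrate A [substrate_characterization()] object.
#' @return A `reactor_schedule` object.
#' @examples
#' reactor_schedule(
#'   working_volume = 5,
#'   periods = data.frame(day_start = c(0, 50), day_end = c(50, 65),
#'                        olr = c(14.2, 23.7), hrt = c(5, 3)),
#'   substrate = mixed_sludge_substrate()
#' )
#' @export
reactor_schedule <- function(working_volume, periods, substrate) {
  stopifnot(inherits(substrate, "substrate_characterization"))
  if (working_volume <= 0) abort("working_volume must be positive (L)")
  periods <- tibble::as_tibble(periods)
  needed <- c("day_start", "day_end", "olr", "hrt")
  if (!all(needed %in% names(periods))) {
    abort(paste0("periods needs columns: ", paste(needed, collapse = ", ")))
  }
  periods <- dplyr::arrange(periods, .data$day_start)
  if (any(periods$olr <= 0) || any(periods$hrt <= 0)) {
    abort("olr and hrt must be positive in every period")
  }
  if (any(periods$day_end <= periods$day_start)) {
    abort("each period needs day_end > day_start")
  }
  if (nrow(periods) > 1L &&
      any(abs(periods$day_start[-1L] -
              periods$day_end[-nrow(periods)]) > 1e-9)) {
    abort("periods must be contiguous and non-overlapping")
  }
  structure(
    list(working_volume = working_volume, periods = periods,
         substrate = substrate),
    class = "reactor_schedule"
  )
}

#' @export
print.reactor_schedule <- function(x, ...) {
  cat(sprintf("<reactor schedule> %.1f L working volume, substrate: %s\n",
              x$working_volume, x$substrate$name))
  print(x$periods)
  invisible(x)
}

#' Normalize a gas volume to standard temperature and pressure
#'
#' Converts a measured gas volume to the normalization convention used for
#' all gas data in the package: 273.2 K and 1.01325 bar, ideal gas. The
#' operation is the identity at STP and linear in the raw volume.
#'
#' @param raw_volume Measured volume, L.
#' @param temp Measurement temperature, K.
#' @param pressure Measurement pressure, bar.
#' @return Volume in L at STP.
#' @examples
#' normalize_gas_volume(1, temp = 310.15, pressure = 1.01325)
#' @export
normalize_gas_volume <- function(raw_volume, temp, pressure) {
  if (any(temp <= 0) || any(pressure <= 0)) {
    abort("temp (K) and pressure (bar) must be positive")
  }
  if (any(raw_volume < 0)) abort("raw_volume must be non-negative")
  raw_volume * (pressure / .const$P_stp) * (.const$T_stp / temp)
}
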