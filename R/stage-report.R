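# Last-observation-carried-forward within a period; sampling gaps (weekends)
# are filled from the latest measurement before averaging.
.locf <- function(x) {
  if (all(is.na(x))) return(x)
  idx <- cumsum(!is.na(x))
  filled <- c(NA, x[!is.na(x)])[idx + 1L]
  filled
}

.period_mean <- function(x) {
  x <- .locf(x)
  if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
}

#' Aggregate one reporting period of reactor observations
#'
#' Computes the period-mean carbon pools needed by the stage-efficiency
#' definitions: residual DOC, VFA carbon (with and without lactate), acetate
#' carbon, gas carbon and methane carbon per litre fed, raw protein, and the
#' VS fed per litre of substrate. Missing daily values are carried forward
#' within the period; period values are arithmetic means over observed days.
#'
#' @param liquid Tibble of daily liquid observations (columns `day`, `ph`,
#'   acid codes `ac, pr, ib, bu, iv, va, ca, hep, lac` in g/L, `doc_res`,
#'   `kjn`, `nh4n` in mg/L; any may be missing).
#' @param gas Tibble of daily gas observations (`day`, `volume_norm` L/d at
#'   STP, `ch4_frac`, `co2_frac`, `h2_frac`).
#' @param schedule A [reactor_schedule()].
#' @param period Row index into `schedule$periods`.
#' @param registry Acid registry.
#' @return One-row tibble of period aggregates.
#' @export
aggregate_period <- function(liquid, gas, schedule, period = 1L,
                             registry = acid_registry()) {
  p <- schedule$periods[period, ]
  last <- period == nrow(schedule$periods)
  in_period <- function(day) {
    day >= p$day_start & (day < p$day_end | (last & day <= p$day_end))
  }
  liq <- dplyr::filter(tibble::as_tibble(liquid), in_period(.data$day))
  gs <- dplyr::filter(tibble::as_tibble(gas), in_period(.data$day))
  feed_volume <- schedule$working_volume / p$hrt

  acid_codes <- intersect(names(.vfa_cols), names(liq))
  vfa_mean <- vapply(acid_codes, function(cc) .period_mean(liq[[cc]]),
                     numeric(1))
  has_vfa <- length(vfa_mean) > 0L && any(!is.na(vfa_mean))

  tc_gases <- ch4_c <- NA_real_
  if (nrow(gs) > 0L) {
    tc_gases <- carbon_in_gas(gs, feed_volume, "both")
    ch4_c <- carbon_in_gas(gs, feed_volume, "ch4")
  }

  kjn <- if ("kjn" %in% names(liq)) .period_mean(liq$kjn) else NA_real_
  nh4n <- if ("nh4n" %in% names(liq)) .period_mean(liq$nh4n) else NA_real_
  rp_hyd <- if (!is.na(kjn) && !is.na(nh4n)) raw_protein(kjn, nh4n) else
    NA_real_

  tibble::tibble(
    day_start = p$day_start, day_end = p$day_end,
    olr = p$olr, hrt = p$hrt, n_liquid_days = nrow(liq),
    n_gas_days = nrow(gs), feed_volume = feed_volume,
    doc_in = schedule$substrate$doc_in, toc_tot = schedule$substrate$toc_tot,
    doc_res = if ("doc_res" %in% names(liq)) .period_mean(liq$doc_res) else
      NA_real_,
    tc_gases = tc_gases, ch4_c = ch4_c,
    toc_vfa = if (has_vfa) vfa_carbon(vfa_mean, FALSE, registry) else
      NA_real_,
    toc_vfa_with_lactate = if (has_vfa) vfa_carbon(vfa_mean, TRUE, registry)
      else NA_real_,
    toc_acetate = if (has_vfa && "ac" %in% acid_codes)
      max(vfa_mean["ac"], 0, na.rm = TRUE) *
        carbon_fraction("acetic", registry) * 1000 else NA_real_,
    acetate_g_l = if ("ac" %in% acid_codes) .period_mean(liq$ac) else
      NA_real_,
    raw_protein_hydrolysate = rp_hyd,
    vs_fed_g_l = p$olr * p$hrt,
    vfa = list(vfa_mean)
  )
}

#' Stage-efficiency report for a reactor experiment
#'
#' Aggregates the time series per operating period and applies the five
#' stage-efficiency definitions: degree of hydrolysis (percent of ingoing
#' TOC), acidogenesis (percent of DOC; lactate-inclusive VFA carbon),
#' acetogenesis (acetate share of VFA carbon, lactate-free by default),
#' protein hydrolysis (percent of ingoing raw protein) and first-stage
#' methanogenesis (CH4 carbon as percent of ingoing TOC). Rows whose inputs
#' are missing carry `NA` with a flag; negative hydrolysis is preserved and
#' flagged as net DOC consumption (methanogenic uptake), not clamped.
#'
#' @inheritParams aggregate_period
#' @param include_lactate Count lactate in acetogenesis' VFA total?
#' @return A tibble with one row per period: the aggregates from
#'   [aggregate_period()] plus `hydrolysis_pct`, `acidogenesis_pct`,
#'   `acetogenesis_pct`, `protein_hydrolysis_pct`, `methanogenesis_1st_pct`,
#'   `acetate_yield_g_kg_vs` and `flags`.
#' @examples
#' truth <- synthetic_truth(preset = "sludge_co")
#' obs <- generate_series(truth, n_days = 30)
#' stage_report(obs$liquid, obs$gas, truth$schedule)
#' @export
stage_report <- function(liquid, gas, schedule, include_lactate = FALSE,
                         registry = acid_registry()) {
  rows <- purrr::map_dfr(seq_len(nrow(schedule$periods)), function(i) {
    agg <- aggregate_period(liquid, gas, schedule, i, registry)
    if (agg$n_liquid_days == 0L && agg$n_gas_days == 0L) {
      warn(sprintf("period %d (%g-%g d) has no observations; skipped",
                   i, agg$day_start, agg$day_end))
      return(NULL)
    }
    flags <- character()
    hyd <- aci <- ace <- prot <- met <- NA_real_

    if (!is.na(agg$doc_res) && !is.na(agg$tc_gases)) {
      hyd <- degree_of_hydrolysis(agg$doc_res, agg$tc_gases,
                                  agg$doc_in, agg$toc_tot)
      if (hyd < 0) flags <- c(flags, "net_doc_consumption")
      aci <- degree_of_acidogenesis(agg$toc_vfa_with_lactate, agg$tc_gases,
                                    agg$doc_res)
    } else {
      flags <- c(flags, "carbon_balance_missing")
    }
    vfa_mean <- agg$vfa[[1L]]
    if (length(vfa_mean) > 0L && any(!is.na(vfa_mean)) &&
        sum(vfa_mean, na.rm = TRUE) > 0) {
      ace <- degree_of_acetogenesis(vfa_mean, include_lactate, registry)
    } else {
      flags <- c(flags, "vfa_missing")
    }
    rp_sub <- raw_protein(schedule$substrate$kjeldahl_n,
                          schedule$substrate$nh4_n)
    if (!is.na(agg$raw_protein_hydrolysate) && !is.na(rp_sub) && rp_sub > 0) {
      prot <- (1 - agg$raw_protein_hydrolysate / rp_sub) * 100
    } else {
      flags <- c(flags, "protein_missing")
    }
    if (!is.na(agg$ch4_c)) {
      met <- degree_of_methanogenesis(agg$ch4_c, agg$toc_tot)
    }
    yield <- if (!is.na(agg$acetate_g_l))
      acid_yield(agg$acetate_g_l, agg$olr, agg$hrt) else NA_real_

    dplyr::mutate(agg,
                  hydrolysis_pct = hyd, acidogenesis_pct = aci,
                  acetogenesis_pct = ace, protein_hydrolysis_pct = prot,
                  methanogenesis_1st_pct = met,
                  acetate_yield_g_kg_vs = yield,
                  flags = paste(flags, collapse = ";"))
  })
  rows
}

#' Format a stage report as an aligned text table
#'
#' One column per period, one row per stage efficiency, mirroring the
#' conventional presentation of two-stage AD carbon balances.
#'
#' @param report Output of [stage_report()].
#' @param digits Digits for percentages.
#' @return Character vector of lines (invisibly printed with `cat`).
#' @export
format_stage_table <- function(report, digits = 0) {
  stages <- c("Hydrolysis" = "hydrolysis_pct",
              "Acidogenesis" = "acidogenesis_pct",
              "Acetogenesis" = "acetogenesis_pct",
              "Protein hydrolysis" = "protein_hydrolysis_pct",
              "Methanogenesis (1st stage)" = "methanogenesis_1st_pct")
  units <- c("of TOC in", "of DOC", "of VFA", "of raw protein in",
             "of TOC in")
  hdr <- sprintf("%g-%g d", report$day_start, report$day_end)
  fmt <- function(v) ifelse(is.na(v), "nd",
                            paste0(formatC(v, digits = digits,
                                           format = "f"), "%"))
  body <- vapply(stages, function(col) fmt(report[[col]]),
                 character(nrow(report)))
  body <- matrix(body, nrow = length(stages), byrow = TRUE,
                 dimnames = list(names(stages), hdr))
  w1 <- max(nchar(rownames(body))) + 2L
  wc <- pmax(nchar(colnames(body)), apply(nchar(body), 2, max)) + 2L
  lines <- c(
    paste0(formatC("Time period", width = w1, flag = "-"),
           paste(mapply(formatC, colnames(body), width = wc),
                 collapse = ""), "  "),
    vapply(seq_along(stages), function(i) {
      paste0(formatC(rownames(body)[i], width = w1, flag = "-"),
             paste(mapply(formatC, body[i, ], width = wc), collapse = ""),
             "  ", units[i])
    }, character(1))
  )
  lines
}
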