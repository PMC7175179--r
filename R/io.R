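# Tidy time-series CSV dialect: one row per reactor-day. Acids in g/L,
# carbon and nitrogen in mg/L, gas in normalized L/d and volume percent.
.ts_cols <- c("day", "reactor", "ph", "ac", "pr", "ib", "bu", "iv", "va",
              "ca", "hep", "lac", "doc_res", "kjn", "nh4n",
              "gas_l", "ch4_pct", "co2_pct", "h2_pct")

#' Read a reactor time series from CSV
#'
#' Expects the tidy dialect written by [write_timeseries()]: columns
#' `day, reactor, ph, ac, pr, ib, bu, iv, va, ca, hep, lac, doc_res, kjn,
#' nh4n, gas_l, ch4_pct, co2_pct, h2_pct` (header mandatory, missing values
#' as empty cells, '.' decimal separator). Rows failing validation
#' (negative concentrations, pH outside (0, 14), gas fractions summing
#' above 1, non-numeric cells) are dropped and itemized, with line numbers,
#' in the `errors` element.
#'
#' @param path CSV file.
#' @return List with tibbles `liquid` (per-day chemistry) and `gas`
#'   (volume as `volume_norm`, fractions 0-1) and a character vector
#'   `errors` (empty when the file is clean).
#' @export
read_timeseries <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  spec <- if ("reactor" %in% hdr)
    readr::cols(reactor = readr::col_character(),
                .default = readr::col_double())
  else readr::cols(.default = readr::col_double())
  raw <- readr::read_csv(path, col_types = spec, progress = FALSE)
  if (nrow(raw) == 0L) abort(paste0("empty time-series file: ", path))
  unknown <- setdiff(names(raw), .ts_cols)
  if (length(unknown) > 0L) {
    abort(paste0("unknown columns in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  if (!"day" %in% names(raw)) abort("time series needs a 'day' column")

  errors <- character()
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    errors <- c(errors, sprintf("line %d: expected %s, got '%s'",
                                probs$row + 1L, probs$expected,
                                probs$actual))
    # readr leaves NA in the affected cells; the rows themselves are kept
  }
  conc_cols <- intersect(c("ac", "pr", "ib", "bu", "iv", "va", "ca", "hep",
                           "lac", "doc_res", "kjn", "nh4n", "gas_l"),
                         names(raw))
  bad <- rep(FALSE, nrow(raw))
  for (cc in conc_cols) {
    neg <- !is.na(raw[[cc]]) & raw[[cc]] < 0
    if (any(neg)) {
      errors <- c(errors, sprintf("line %d: negative %s (%g)",
                                  which(neg) + 1L, cc, raw[[cc]][neg]))
      bad <- bad | neg
    }
  }
  if ("ph" %in% names(raw)) {
    offr <- !is.na(raw$ph) & (raw$ph <= 0 | raw$ph >= 14)
    if (any(offr)) {
      errors <- c(errors, sprintf("line %d: pH %g outside (0, 14)",
                                  which(offr) + 1L, raw$ph[offr]))
      bad <- bad | offr
    }
  }
  pct_cols <- intersect(c("ch4_pct", "co2_pct", "h2_pct"), names(raw))
  if (length(pct_cols) > 0L) {
    tot <- rowSums(as.matrix(raw[, pct_cols]), na.rm = TRUE)
    over <- tot > 100 + 1e-6
    if (any(over)) {
      errors <- c(errors, sprintf("line %d: gas fractions sum to %.1f%%",
                                  which(over) + 1L, tot[over]))
      bad <- bad | over
    }
  }
  raw <- raw[!bad, ]
  if (nrow(raw) == 0L) abort("no valid rows after validation")

  liquid_cols <- intersect(c("day", "reactor", "ph", "ac", "pr", "ib", "bu",
                             "iv", "va", "ca", "hep", "lac", "doc_res",
                             "kjn", "nh4n"), names(raw))
  gas <- NULL
  if ("gas_l" %in% names(raw)) {
    gas <- tibble::tibble(
      day = raw$day,
      volume_norm = raw$gas_l,
      ch4_frac = if ("ch4_pct" %in% names(raw)) raw$ch4_pct / 100 else
        NA_real_,
      co2_frac = if ("co2_pct" %in% names(raw)) raw$co2_pct / 100 else
        NA_real_,
      h2_frac = if ("h2_pct" %in% names(raw)) raw$h2_pct / 100 else NA_real_)
    if ("reactor" %in% names(raw)) gas$reactor <- raw$reactor
    gas <- gas[!is.na(gas$volume_norm), ]
  }
  list(liquid = raw[, liquid_cols], gas = gas, errors = errors)
}

#' Write a reactor time series to CSV
#'
#' Inverse of [read_timeseries()]: merges the liquid and gas tables on
#' `day` (and `reactor` when present) into the tidy one-row-per-reactor-day
#' dialect.
#'
#' @param liquid,gas Tibbles as produced by [generate_series()].
#' @param path Output CSV file.
#' @param reactor Reactor label to write when the tables carry none.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(liquid, gas, path, reactor = "R1") {
  liquid <- tibble::as_tibble(liquid)
  if (!"reactor" %in% names(liquid)) liquid$reactor <- reactor
  out <- liquid
  if (!is.null(gas)) {
    gas <- tibble::as_tibble(gas)
    if (!"reactor" %in% names(gas)) gas$reactor <- reactor
    gtab <- tibble::tibble(day = gas$day, reactor = gas$reactor,
                           gas_l = gas$volume_norm,
                           ch4_pct = gas$ch4_frac * 100,
                           co2_pct = gas$co2_frac * 100,
                           h2_pct = gas$h2_frac * 100)
    out <- dplyr::full_join(out, gtab, by = c("day", "reactor"))
  }
  keep <- intersect(.ts_cols, names(out))
  readr::write_csv(out[order(out$day), keep], path, na = "")
  invisible(path)
}

#' Write a BMP bottle set to CSV / read it back
#'
#' Long format `bottle,role,substrate_mass_g,substrate_vs_g,inoculum_vs_g,
#' day,ml_ch4`.
#'
#' @param set A [bmp_set()].
#' @param path CSV file.
#' @return `write_bmp_csv()` returns `path` invisibly; `read_bmp_csv()` a
#'   [bmp_set()].
#' @export
write_bmp_csv <- function(set, path) {
  stopifnot(inherits(set, "bmp_set"))
  long <- dplyr::inner_join(set$bottles, set$curves, by = "label")
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_bmp_csv
#' @export
read_bmp_csv <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), role = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  bottles <- dplyr::distinct(
    long[, c("label", "role", "substrate_mass_g", "substrate_vs_g",
             "inoculum_vs_g")])
  bmp_set(bottles, long[, c("label", "day", "ml_ch4")])
}

#' Run the full acid-stage analysis pipeline
#'
#' Reads (or accepts) a reactor time series, computes the per-period stage
#' report, acetate yield and acid speciation at the observed pH, and writes
#' a report bundle: `stage_report.csv`, `stage_table.txt`,
#' `speciation.csv`, `yields.csv` and `run_log.txt` (package version, seed,
#' acid-registry hash, input provenance). Validation errors propagate;
#' nothing is swallowed.
#'
#' @param input Path to a time-series CSV, or the list returned by
#'   [generate_series()] / [read_timeseries()].
#' @param schedule A [reactor_schedule()].
#' @param out_dir Output directory (created if needed).
#' @param include_lactate Passed to [stage_report()].
#' @param speciation_method `"both"`, `"hh"` or `"ostwald"`.
#' @param registry Acid registry.
#' @param seed Recorded in the run log (the analysis itself is
#'   deterministic).
#' @return List with `report`, `speciation`, `yields` and the output paths,
#'   invisibly.
#' @export
run_pipeline <- function(input, schedule, out_dir,
                         include_lactate = FALSE,
                         speciation_method = c("both", "hh", "ostwald"),
                         registry = acid_registry(), seed = NA_integer_) {
  speciation_method <- match.arg(speciation_method)
  if (is.character(input)) {
    src <- input
    ts <- read_timeseries(input)
    if (length(ts$errors) > 0L) {
      abort(paste0("input validation failed:\n  ",
                   paste(ts$errors, collapse = "\n  ")))
    }
  } else {
    src <- "<in-memory>"
    ts <- input
  }
  report <- stage_report(ts$liquid, ts$gas, schedule,
                         include_lactate = include_lactate,
                         registry = registry)

  spec_rows <- purrr::map_dfr(seq_len(nrow(report)), function(i) {
    ac <- report$acetate_g_l[i]
    if (is.na(ac) || ac <= 0) return(NULL)
    agg_liq <- dplyr::filter(tibble::as_tibble(ts$liquid),
                             .data$day >= report$day_start[i],
                             .data$day <= report$day_end[i])
    ph <- .period_mean(agg_liq$ph)
    sp <- speciate(ac, "acetic",
                   ph = if (speciation_method == "ostwald") NULL else ph,
                   method = speciation_method, registry = registry)
    dplyr::mutate(sp, day_start = report$day_start[i],
                  day_end = report$day_end[i], acetate_g_l = ac,
                  .before = 1)
  })

  yields <- report[, c("day_start", "day_end", "olr", "hrt", "acetate_g_l",
                       "acetate_yield_g_kg_vs")]

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    stage_report = file.path(out_dir, "stage_report.csv"),
    stage_table = file.path(out_dir, "stage_table.txt"),
    speciation = file.path(out_dir, "speciation.csv"),
    yields = file.path(out_dir, "yields.csv"),
    log = file.path(out_dir, "run_log.txt"))
  readr::write_csv(dplyr::select(report, -"vfa"), paths$stage_report)
  writeLines(format_stage_table(report), paths$stage_table)
  readr::write_csv(spec_rows, paths$speciation)
  readr::write_csv(yields, paths$yields)
  writeLines(c(
    sprintf("adcarbon %s", as.character(utils::packageVersion("adcarbon"))),
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("input: %s", src),
    sprintf("seed: %s", seed),
    sprintf("acid registry hash: %s", registry_hash(registry)),
    sprintf("include_lactate: %s", include_lactate),
    sprintf("speciation method: %s", speciation_method)), paths$log)

  invisible(list(report = report, speciation = spec_rows, yields = yields,
                 paths = paths))
}
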