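#' Acid-species registry
#'
#' Constants for the weak acids (and glucose) handled by the carbon
#' bookkeeping: molar mass, carbon count, and pKa at ~25 degrees C.
#' `in_total_vfa` marks whether a species counts towards "total VFA" in
#' acetogenesis calculations; lactate is excluded by default because
#' acetate-fraction figures in acidogenic reactors are conventionally quoted
#' on a lactate-free basis, while lactate still counts as acidified dissolved
#' carbon. Glucose carries no pKa (it is not an acid) and never counts as VFA.
#'
#' @param overrides Optional tibble/data.frame with the same columns as the
#'   registry; rows replace the shipped entry with the same `name`, or are
#'   appended if the name is new.
#' @return A tibble with columns `name`, `formula`, `molar_mass` (g/mol),
#'   `n_carbon`, `pka`, `in_total_vfa`, `carbon_fraction`.
#' @examples
#' acid_registry()
#' carbon_fraction("acetic")
#' @export
acid_registry <- function(overrides = NULL) {
  reg <- tibble::tribble(
    ~name,        ~formula,   ~molar_mass, ~n_carbon, ~pka,  ~in_total_vfa,
    "acetic",     "C2H4O2",    60.05,      2L,        4.756, TRUE,
    "propionic",  "C3H6O2",    74.08,      3L,        4.87,  TRUE,
    "butyric",    "C4H8O2",    88.11,      4L,        4.82,  TRUE,
    "valeric",    "C5H10O2",  102.13,      5L,        4.84,  TRUE,
    "caproic",    "C6H12O2",  116.16,      6L,        4.88,  TRUE,
    "heptanoic",  "C7H14O2",  130.18,      7L,        4.89,  TRUE,
    "lactic",     "C3H6O3",    90.08,      3L,        3.86,  FALSE,
    "glucose",    "C6H12O6",  180.16,      6L,        NA,    FALSE
  )
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    needed <- c("name", "molar_mass", "n_carbon")
    if (!all(needed %in% names(overrides))) {
      abort(paste0("registry overrides need columns: ",
                   paste(needed, collapse = ", ")))
    }
    if (!"formula" %in% names(overrides)) overrides$formula <- NA_character_
    if (!"pka" %in% names(overrides)) overrides$pka <- NA_real_
    if (!"in_total_vfa" %in% names(overrides)) overrides$in_total_vfa <- TRUE
    reg <- dplyr::bind_rows(
      dplyr::filter(reg, !.data$name %in% overrides$name),
      overrides[, names(reg)]
    )
  }
  reg$carbon_fraction <- reg$n_carbon * .const$M_C / reg$molar_mass
  # (0, 1] — the upper bound admits the pure-carbon limit
  bad <- reg$carbon_fraction <= 0 | reg$carbon_fraction > 1 + 1e-12
  if (any(bad)) {
    abort(paste0("carbon fraction outside (0,1] for: ",
                 paste(reg$name[bad], collapse = ", ")))
  }
  reg
}

#' Look up one species in a registry
#'
#' @param name Species name (e.g. `"acetic"`).
#' @param registry A registry tibble, default [acid_registry()].
#' @return One-row tibble.
#' @export
acid_species <- function(name, registry = acid_registry()) {
  hit <- registry[registry$name == name, ]
  if (nrow(hit) != 1L) {
    abort(paste0("unknown acid species: '", name, "' (registry has: ",
                 paste(registry$name, collapse = ", "), ")"))
  }
  hit
}

#' Carbon mass fraction of a species
#'
#' The fraction of a species' molar mass contributed by carbon,
#' `n_carbon * 12.011 / molar_mass`. Acetate and lactate share the empirical
#' formula CH2O and therefore the same carbon fraction (0.4001).
#'
#' @inheritParams acid_species
#' @return Numeric fraction in (0, 1).
#' @export
carbon_fraction <- function(name, registry = acid_registry()) {
  acid_species(name, registry)$carbon_fraction
}

#' Write / read the acid registry as a versioned YAML config
#'
#' Users can persist a modified registry and reload it, so reported
#' efficiencies are traceable to the constants used. The file carries a
#' format version and the registry content hash is available via
#' [registry_hash()].
#'
#' @param registry Registry tibble.
#' @param path File path.
#' @return `write_acid_registry()` returns `path` invisibly;
#'   `read_acid_registry()` returns the registry tibble.
#' @export
write_acid_registry <- function(registry, path) {
  species <- purrr::pmap(
    registry[, c("name", "formula", "molar_mass", "n_carbon", "pka",
                 "in_total_vfa")],
    function(name, formula, molar_mass, n_carbon, pka, in_total_vfa) {
      list(name = name, formula = formula, molar_mass = molar_mass,
           n_carbon = n_carbon, pka = if (is.na(pka)) NULL else pka,
           in_total_vfa = in_total_vfa)
    }
  )
  yaml::write_yaml(list(format = "adcarbon-acid-registry", version = 1L,
                        species = species), path)
  invisible(path)
}

#' @rdname write_acid_registry
#' @export
read_acid_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$format, "adcarbon-acid-registry")) {
    abort(paste0("not an acid-registry file: ", path))
  }
  rows <- purrr::map_dfr(raw$species, function(sp) {
    tibble::tibble(
      name = sp$name, formula = sp$formula %||% NA_character_,
      molar_mass = sp$molar_mass, n_carbon = as.integer(sp$n_carbon),
      pka = sp$pka %||% NA_real_, in_total_vfa = isTRUE(sp$in_total_vfa)
    )
  })
  rows$carbon_fraction <- rows$n_carbon * .const$M_C / rows$molar_mass
  rows
}

#' @rdname write_acid_registry
#' @export
registry_hash <- function(registry) {
  rlang::hash(registry[, c("name", "molar_mass", "n_carbon", "pka",
                           "in_total_vfa")])
}
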