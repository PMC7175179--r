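#' Assemble a BMP bottle set
#'
#' A biochemical-methane-potential assay as two tidy tables: bottle metadata
#' and cumulative methane curves. Roles are `sample`, `blank` (inoculum
#' only) or `control` (positive control, e.g. crystalline cellulose).
#'
#' @param bottles Tibble with columns `label`, `role`, `substrate_mass_g`
#'   (g wet material), `substrate_vs_g` (g VS), `inoculum_vs_g` (g VS).
#'   Blanks must carry no substrate.
#' @param curves Long tibble with columns `label`, `day`, `ml_ch4`
#'   (cumulative mL CH4 at STP, non-decreasing).
#' @return A `bmp_set` object.
#' @export
bmp_set <- function(bottles, curves) {
  bottles <- tibble::as_tibble(bottles)
  curves <- tibble::as_tibble(curves)
  stopifnot(all(c("label", "role", "substrate_mass_g", "substrate_vs_g",
                  "inoculum_vs_g") %in% names(bottles)),
            all(c("label", "day", "ml_ch4") %in% names(curves)))
  if (!all(bottles$role %in% c("sample", "blank", "control"))) {
    abort("bottle role must be sample, blank or control")
  }
  blk <- bottles$role == "blank"
  if (any(blk & (bottles$substrate_mass_g > 0 | bottles$substrate_vs_g > 0),
          na.rm = TRUE)) {
    abort("blank bottles must carry no substrate")
  }
  if (!all(curves$label %in% bottles$label)) {
    abort("curves reference unknown bottle labels")
  }
  dec <- curves |>
    dplyr::arrange(.data$label, .data$day) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(ok = all(diff(.data$ml_ch4) >= -1e-9))
  if (!all(dec$ok)) {
    warn(paste0("non-monotone cumulative curve(s): ",
                paste(dec$label[!dec$ok], collapse = ", "),
                "; running maximum will be used downstream"))
  }
  structure(list(bottles = bottles, curves = curves), class = "bmp_set")
}

#' @export
print.bmp_set <- function(x, ...) {
  cat(sprintf("<bmp set> %d bottles (%s), %d curve points\n",
              nrow(x$bottles),
              paste(sprintf("%d %s", table(x$bottles$role),
                            names(table(x$bottles$role))), collapse = ", "),
              nrow(x$curves)))
  invisible(x)
}

.bottle_curve <- function(set, label) {
  cv <- dplyr::arrange(set$curves[set$curves$label == label, ], .data$day)
  if (nrow(cv) == 0L) abort(paste0("no curve for bottle ", label))
  cv
}

#' Blank-corrected methane curve for one bottle
#'
#' Subtracts the mean blank (inoculum-only) contribution, scaled by the
#' sample's inoculum VS relative to the blanks': the inoculum's endogenous
#' methane per gram of its VS is assumed equal across bottles of a cohort.
#' Negative net values are kept (and are expected early for weak substrates);
#' nothing is clamped.
#'
#' @param set A [bmp_set()].
#' @param label Bottle to correct.
#' @return Tibble `day`, `ml_ch4_net`.
#' @export
net_methane <- function(set, label) {
  stopifnot(inherits(set, "bmp_set"))
  sample_row <- set$bottles[set$bottles$label == label, ]
  if (nrow(sample_row) != 1L) abort(paste0("unknown bottle: ", label))
  cv <- .bottle_curve(set, label)
  blanks <- set$bottles[set$bottles$role == "blank", ]
  if (nrow(blanks) == 0L) abort("bmp set has no blank bottles")
  if (sample_row$inoculum_vs_g == 0) {
    return(tibble::tibble(day = cv$day, ml_ch4_net = cv$ml_ch4))
  }
  per_g <- purrr::map(blanks$label, function(bl) {
    b <- .bottle_curve(set, bl)
    if (!isTRUE(all.equal(b$day, cv$day))) {
      abort("blank and sample day grids differ; resample before correcting")
    }
    b$ml_ch4 / blanks$inoculum_vs_g[blanks$label == bl]
  })
  blank_per_g <- Reduce(`+`, per_g) / length(per_g)
  tibble::tibble(day = cv$day,
                 ml_ch4_net = cv$ml_ch4 -
                   sample_row$inoculum_vs_g * blank_per_g)
}

#' Mass-loss fraction of the acid stage
#'
#' When a hydrolysate is compared with its fresh substrate per gram of
#' material, the grams of hydrolysate no longer equal the grams of substrate
#' fed: CH4, CO2 (and traces of H2) produced during the acid stage left as
#' gas. This computes the fraction of fed wet mass lost as gas from the
#' per-litre gas production of the acid stage.
#'
#' @param ch4_c,co2_c Methane / carbon-dioxide carbon, mg C per L substrate
#'   fed (e.g. from [carbon_in_gas()] with `species = "ch4"` / `"co2"`).
#' @param h2_mol Optional H2 production, mol per L substrate fed.
#' @param density Substrate density, kg/L.
#' @return Fraction of fed wet mass leaving as gas. Values outside the
#'   plausible 0-0.2 band trigger a warning.
#' @export
mass_loss_fraction <- function(ch4_c, co2_c, h2_mol = 0, density = 1.0) {
  gas_g <- (ch4_c / 1000 / .const$M_C) * .const$M_CH4 +
    (co2_c / 1000 / .const$M_C) * .const$M_CO2 +
    h2_mol * .const$M_H2
  frac <- gas_g / (1000 * density)
  if (frac < 0 || frac > 0.2) {
    warn(sprintf("mass-loss fraction %.3f outside the plausible 0-0.2 band",
                 frac))
  }
  frac
}

#' Methane potential per gram
#'
#' Plateau net methane (cumulative volume at the final incubation day) per
#' gram of material or of volatile solids, averaged over sample bottles with
#' a Student-t confidence interval. For hydrolysates compared per gram of
#' original substrate fed (`as_fed = TRUE`), the per-gram-of-hydrolysate
#' value is mapped onto the fed-material basis by multiplying by
#' `(1 - mass_loss_fraction)`; skipping this compensation overstates the
#' hydrolysate because the same methane is divided over fewer grams.
#'
#' @param set A [bmp_set()].
#' @param basis `"material"` (per g wet material) or `"vs"` (per g VS).
#' @param as_fed Express a hydrolysate per gram of original substrate fed?
#' @param mass_loss_fraction Fraction of fed wet mass lost as gas in the
#'   acid stage (see [mass_loss_fraction()]); required when `as_fed = TRUE`.
#' @param roles Bottle roles to evaluate (default `"sample"`).
#' @return List with `per_bottle` (tibble `label`, `ml_per_g`), `mean`,
#'   `ci_half_width`, `n`, `basis`, `as_fed`.
#' @export
bmp_per_gram <- function(set, basis = c("material", "vs"), as_fed = FALSE,
                         mass_loss_fraction = NULL, roles = "sample") {
  basis <- match.arg(basis)
  stopifnot(inherits(set, "bmp_set"))
  if (as_fed && is.null(mass_loss_fraction)) {
    abort(paste0("per-gram-fed basis for a hydrolysate needs the acid ",
                 "stage's mass-loss fraction"))
  }
  samples <- set$bottles[set$bottles$role %in% roles, ]
  if (nrow(samples) == 0L) abort("no bottles with the requested role")
  per_bottle <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    b <- samples[i, ]
    grams <- switch(basis, material = b$substrate_mass_g,
                    vs = b$substrate_vs_g)
    if (is.na(grams) || grams <= 0) {
      abort(paste0("bottle ", b$label, " has no positive ", basis, " mass"))
    }
    net <- net_methane(set, b$label)
    plateau <- cummax(net$ml_ch4_net)[nrow(net)]
    v <- plateau / grams
    if (as_fed) v <- v * (1 - mass_loss_fraction)
    tibble::tibble(label = b$label, ml_per_g = v)
  })
  n <- nrow(per_bottle)
  ci <- if (n >= 2L) confidence_interval(per_bottle$ml_per_g) else
    list(mean = mean(per_bottle$ml_per_g), half_width = NA_real_, n = n)
  list(per_bottle = per_bottle, mean = ci$mean,
       ci_half_width = ci$half_width, n = n, basis = basis, as_fed = as_fed)
}

#' Second-stage methanogenesis from a BMP result
#'
#' Converts a methane potential (mL CH4 per g material) into the share of
#' the substrate's ingoing TOC recovered as methane carbon in the
#' methanogenic stage: mL/g -> mL/L substrate (via density) -> mol CH4 ->
#' mg C, divided by TOC.
#'
#' @param ml_ch4_per_g Net methane potential, mL CH4 (STP) per g material,
#'   or the result list of [bmp_per_gram()] on the material basis.
#' @param substrate A [substrate_characterization()].
#' @return Percent of ingoing TOC.
#' @examples
#' methanogenesis_2nd_stage(22.414, mixed_sludge_substrate())
#' @export
methanogenesis_2nd_stage <- function(ml_ch4_per_g, substrate) {
  stopifnot(inherits(substrate, "substrate_characterization"))
  if (is.list(ml_ch4_per_g)) ml_ch4_per_g <- ml_ch4_per_g$mean
  if (substrate$toc_tot <= 0) abort("substrate toc_tot must be positive")
  ml_per_l <- ml_ch4_per_g * 1000 * substrate$density
  mg_c <- (ml_per_l / 1000) / .const$molar_vol * .const$M_C * 1000
  mg_c / substrate$toc_tot * 100
}

#' Kinetic summary of a cumulative methane curve
#'
#' Descriptive statistics: plateau (maximum cumulative volume), t50 (first
#' day reaching half the plateau, linearly interpolated between sampling
#' days) and the initial rate (mean daily increment over days 0-5).
#'
#' @param curve Tibble with `day` and a cumulative volume column (`ml_ch4`
#'   or `ml_ch4_net`).
#' @return List `plateau`, `t50` (`NA` when the plateau is zero),
#'   `initial_rate`.
#' @export
kinetic_summary <- function(curve) {
  curve <- tibble::as_tibble(curve)
  vcol <- intersect(c("ml_ch4_net", "ml_ch4"), names(curve))[1]
  if (is.na(vcol)) abort("curve needs an ml_ch4 or ml_ch4_net column")
  curve <- dplyr::arrange(curve, .data$day)
  if (nrow(curve) < 3L) abort("kinetic summary needs >= 3 curve points")
  v <- curve[[vcol]]
  if (any(diff(v) < -1e-9)) {
    warn("non-monotone cumulative curve; using running maximum")
    v <- cummax(v)
  }
  plateau <- max(v)
  t50 <- NA_real_
  if (plateau > 0) {
    half <- plateau / 2
    i <- which(v >= half)[1L]
    if (i == 1L) {
      t50 <- curve$day[1L]
    } else {
      d0 <- curve$day[i - 1L]; d1 <- curve$day[i]
      v0 <- v[i - 1L]; v1 <- v[i]
      t50 <- d0 + (half - v0) / (v1 - v0) * (d1 - d0)
    }
  }
  early <- curve$day <= 5
  span <- max(curve$day[early]) - min(curve$day[early])
  rate <- if (sum(early) >= 2L && span > 0)
    (v[which(early)[sum(early)]] - v[which(early)[1L]]) / span else NA_real_
  list(plateau = plateau, t50 = t50, initial_rate = rate)
}
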