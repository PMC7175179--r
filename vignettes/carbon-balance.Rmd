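---
title: "Carbon mass balance for two-stage anaerobic digestion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon mass balance for two-stage anaerobic digestion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcarbon)
```

## The model

Two-stage anaerobic digestion splits the microbial food chain in two: an
acidogenic reactor run at short retention and high load, where hydrolysis
and fermentation dominate and methanogens are (ideally) washed out, and a
methanogenic stage fed the resulting hydrolysate. `adcarbon` treats the
acid stage as a carbon-partitioning device and asks, per operating period,
where the ingoing organic carbon went.

The bookkeeping runs on five pools, all in mg C per litre of substrate fed:
ingoing dissolved carbon `DOC_in`, total ingoing carbon `TOC_tot`, residual
dissolved carbon `DOC_res` in the hydrolysate, carbon leaving as CH4 + CO2
(`TC_gases`), and carbon held in fermentation acids (`TOC_VFA`, from
per-species concentrations times registry carbon fractions). The stage
efficiencies are ratios of these pools:

* **Hydrolysis** `(DOC_res + TC_gases - DOC_in) / (TOC_tot - DOC_in)`:
  what fraction of the *particulate* carbon was solubilized. Gas carbon is
  added back to the numerator because carbon that was solubilized and then
  fermented all the way to gas would otherwise be invisible.
* **Acidogenesis** `(TOC_VFA + TC_gases) / (DOC_res + TC_gases)`: what
  fraction of the available dissolved carbon was converted to acids,
  counting gasified carbon as having passed through acids.
* **Acetogenesis** `TOC_acetate / TOC_VFA`: acetate's share of the acid
  carbon.
* **Protein hydrolysis** `1 - RP_hyd / RP_sub`, with raw protein
  `RP = (Kjeldahl-N - NH4-N) * 6.25`.
* **Methanogenesis (1st stage)** `CH4_C / TOC_tot`: the leak of carbon to
  methane inside the acid stage.

Assumptions worth stating: the reactor is a semi-continuous CSTR at steady
state within each period, so outgoing concentrations stand in for produced
concentrations; substrate density is 1.0 kg/L unless overridden, putting
per-kg and per-L bases on the same footing; gas is ideal and normalized to
273.2 K / 1.01325 bar (22.414 L/mol); and carbon fractions of the acids
come from molecular formulae (`n_C * 12.011 / M`), not from TOC
measurements of standards.

### Where lactate counts

Lactate sits awkwardly between conventions: acetate-fraction figures for
acidogenic reactors are typically quoted against "total VFA excluding
lactic acid", while in a *carbon partition* of acidified DOC lactate
plainly counts. The package keeps both books: `degree_of_acidogenesis()`
receives the lactate-inclusive VFA carbon (it is a carbon partition), while
`degree_of_acetogenesis()` excludes lactate by default and takes
`include_lactate = TRUE` where the other convention is wanted. The
synthetic generator is constructed so both identities hold simultaneously,
which is what makes the round-trip tests exact.

### Period aggregation

Reported efficiencies are computed on period-mean aggregates — the ratio of
means, not the mean of daily ratios — because the denominators (notably
`DOC_res` and gas volume) are noisy, and a ratio of means is the stabler
estimator for a multi-week summary. Sampling gaps within a period are
filled by carrying the last observation forward before averaging; this
mimics how bench campaigns (5 measuring days per week) are actually
summarized. Negative hydrolysis values are *reported*, flagged
`net_doc_consumption`: they are physically meaningful (methanogens eating
released DOC faster than hydrolysis supplies it), and clamping them would
hide exactly the failure mode the statistic exists to reveal.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| pKa (per acid) | — | registry, ~25 °C literature values | Speciation is evaluated at the user's pKa; reactors often run at 38 °C and no temperature correction is imposed (a hook, not a hidden constant). |
| Molar volume | L/mol | 22.414 | Matches the 273.2 K / 1.01325 bar normalization of the gas data. |
| Substrate density | kg/L | 1.0 | Slurries near water density; a field on the substrate, not a constant. |
| `include_lactate` | flag | `FALSE` (acetogenesis) | See above. |
| CH4 energy density | kWh/kg | 13.9 (50 MJ/kg LHV) | Scale-up energy values are sometimes quoted on a per-Nm³ basis that back-solves to ≈9.04 kWh/kg; that is selectable, never silently substituted. |
| CH4 per acetate | kg/kg | 16.043/60.05 ≈ 0.267 | Acetoclastic stoichiometry CH3COOH → CH4 + CO2 for foregone methane. |

## Acid speciation: two routes, both reported

The undissociated (protonated) acid is the membrane-permeant, potentially
inhibitory form. Two routes to it are provided:

* **Henderson–Hasselbalch**, `c / (1 + 10^(pH - pKa))`, conditioned on the
  *measured* pH — correct when the pH is known, whatever set it.
* **Ostwald's dilution law**, solving `Ka = α²c/(1-α)` for the acid alone
  in water — correct when no pH measurement exists, and it reports the pH
  it implies.

For a real hydrolysate (a mixture of acids plus buffering matrix) the two
disagree: at 20 g/L acetate and pH 3.9 the pH-conditioned route gives
17.55 g/L undissociated and the dilution-law route 19.86 g/L. Literature
values computed with unstated constants tend to fall between them, which
is why `speciate()` prints both with their pH rather than guessing a
route. The quadratic closed form is verified against a bisection
root-finder across `c ∈ [1e-4, 1]` mol/L, `Ka ∈ [1e-6, 1e-3]` to 1e-10.

The dilution-inhibition analysis (`dilution_linear_fit()`) formalizes a
simple argument: if the undissociated acid level were limiting production,
diluting the hydrolysate would *unlock* production and the
acetate-vs-fraction response would bow above the line at low fractions.
Linearity (R² ≈ 1) is therefore evidence of no toxicity limitation.
Curvature is tested on the quadratic coefficient of a second-order OLS fit
at α = 0.05; a zero-variance response is reported as degenerate with R²
undefined, not 0 or 1.

## BMP analysis

Bottle curves are blank-corrected by the mean blank production *per gram of
inoculum VS*, scaled to each sample's inoculum VS — the endogenous activity
of an inoculum scales with how much of it is in the bottle, not with how
many bottles were run. The plateau is the cumulative volume at the final
incubation day (a fixed 15-day horizon), not a model-fit asymptote: with
first-order kinetics at `k = 0.3/d` this undershoots the ultimate yield by
the unfinished tail `e^(-15k)` ≈ 1.1%, which the recovery tests account for
explicitly rather than hiding in a fitted extrapolation.

Comparing hydrolysate against fresh substrate **per gram of material**
needs a mass-loss compensation: gas produced in the acid stage removed mass,
so a gram of hydrolysate represents more than a gram of original feed.
`mass_loss_fraction()` computes the lost mass from the acid stage's gas
production (Σ mol·M over CH4, CO2, H2 per litre fed) and
`bmp_per_gram(as_fed = TRUE)` maps per-g-hydrolysate onto per-g-fed by
multiplying by `(1 - loss)`. The compensation is the identity at zero loss
and monotone decreasing in the loss — both property-tested.

Second-stage methanogenesis is derived from the BMP result as CH4 carbon
per ingoing TOC (`mL/g → mol → mg C`), an interpretation made explicit in
`methanogenesis_2nd_stage()` since carbon-balance and BMP bookkeeping meet
only through this conversion.

## The synthetic generator

`synthetic_truth()` encodes the stage efficiencies as generative
parameters and `generate_series()` emits daily observation tables with, in
noise-free mode, the property that `stage_report()` returns the truth
*exactly*. The carbon flow per period:

```
released   = eta_h * (TOC - DOC_in)          pool = DOC_in + released
CH4_C      = eta_m * TOC
CO2_C      = co2_to_ch4_c * CH4_C + f_co2_ferm * (eta_a * pool)
TC_gases   = CH4_C + CO2_C                   DOC_res = pool - TC_gases
standing   = eta_a * pool - TC_gases         (acid carbon still in solution)
lactate_C  = lactate_share * standing
acetate_C  = phi * (standing - lactate_C);   rest split by vfa_mix
```

Infeasible combinations (gas carbon exceeding the dissolved pool or the
acidified carbon) fail at construction. Daily carbon conservation —
`DOC_res + TC_gases + unreleased particulate = TOC_tot` — holds to 1e-9
and is property-tested across all presets.

Design choices a user should know:

* **Noise** is multiplicative mean-one lognormal per observable per day
  (CV-parameterized), the standard positivity-preserving error model for
  analytical chemistry replicates; BMP curves apply it to daily
  *increments* so cumulative curves stay monotone.
* **pH** is emitted by a fixed empirical monotone map,
  `pH = clamp(7.6 - 0.115 * total acid g/L, 3.5, 7.8)`, calibrated to pass
  near pH 6.1 at sludge-like acid levels (~14 g/L) and pH 3.9 at
  food-waste-like levels (~32 g/L). Nothing downstream consumes pH except
  speciation; no mechanistic pH model is attempted.
* **Nitrogen**: substrate Kjeldahl-N and NH4-N are not part of the carbon
  characterizations, so the presets assume field-plausible values (food
  waste 4500/150, mixed sludge 3000/600 mg N/L); they set protein levels
  only and do not feed back into the carbon balance.
* **Presets** `sludge_co`, `sludge_ww`, `food_waste_co`, `food_waste_ww`
  encode the four canonical bench configurations (two inocula × two feeds)
  with two operating periods each and efficiency parameters at the levels
  such reactors reach. One schedule note: sludge reactors run
  OLR 14.2 → 23.7 kg VS/m³/d with HRT 5 → 3 d; food-waste reactors
  27 → 13.5 kg VS/m³/d with HRT 5 → 10 d (the long CO-inoculum food-waste
  run keeps HRT 10 d through day 200).
* The generator emulates steady-state periods with stationary noise. It
  does **not** emulate start-up transients, slow washout drifts, pH-VFA
  feedback, or correlated instrument error. Passing round-trip tests
  therefore demonstrates the *accounting* is right and noise-robust, not
  that the package can segment non-stationary campaigns into periods — the
  user supplies period boundaries.

The dilution generator's toxicity regime adds a concave bump
`toxicity_amp * f * (1 - f)`; a design-stage power analysis fixed the test
conditions at triplicate readings on the five-level dilution design with
noise sd 0.15 g/L (the level that reproduces R² ≈ 0.9997 linearity) and a
5 g/L bump, where the quadratic-coefficient t-test detects curvature
essentially always.

## Numerical choices and degenerate inputs

* Efficiency ratios refuse undefined denominators (`TOC ≤ DOC_in`,
  `DOC_res + TC_gases = 0`, all-zero VFA) with explicit errors rather than
  returning NaN.
* The Ostwald quadratic uses the numerically safe positive root
  `(-Ka + sqrt(Ka² + 4cKa)) / 2c`; conservation
  (undissociated + dissociated = total) is exact by construction in the
  Henderson–Hasselbalch route.
* Scale-up reporting rounds to 2 significant figures for display only;
  downstream arithmetic always uses raw values.
* CSV readers collect row-level validation failures (negative
  concentrations, pH outside (0, 14), gas fractions summing past 100%)
  with line numbers instead of failing on the first, and `run_pipeline()`
  refuses to analyse a file with any.
* Seeds: every generator takes an integer seed, uses R's default RNG
  locally, and restores the caller's RNG state.

## Problem sizes

The shipped tests run the round-trip recovery at 30 days × 100 seeds
(5% CV), BMP recovery at 200 seeds of triplicate bottles over a 15-day
grid, and the dilution power check at 500 seeds — sizes at which the Monte
Carlo error on the checked statistics is comfortably below the margins
being asserted, while the whole suite stays under a minute of simulation.

## Known limitations

* COD-based balances, ODE reactor models and pH prediction are out of
  scope; the package is an accounting layer, not a process simulator.
* Activity coefficients and ionic-strength corrections are not applied in
  speciation; at hydrolysate ionic strengths the undissociated fractions
  carry corresponding uncertainty (one reason both routes are printed).
* BMP plateaus are horizon-limited, not extrapolated (no Gompertz /
  first-order fits); comparisons between bottle sets should share the
  incubation horizon.
* Multi-acid coupled equilibria are not solved; speciation treats each
  acid independently at the given pH.
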