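# adcarbon

Carbon mass-balance analysis for two-stage anaerobic digestion (AD).

## The problem

In two-stage AD, a first acidogenic reactor hydrolyses and ferments an
organic feed (food waste, sewage sludge) into volatile fatty acids (VFA) —
above all acetate, a platform chemical worth extracting — and a second,
methanogenic stage converts the remainder to biogas. Judging such a process
requires following the *carbon*: how much of the ingoing total organic
carbon (TOC) is solubilized, how much of the dissolved pool ends up in
acids, what share of the acid carbon is acetate, and how much leaks to
methane already in the acid stage. `adcarbon` implements this bookkeeping
for bench reactor time series (liquid chemistry + normalized gas
production), together with the side analyses that belong to it: weak-acid
speciation (the undissociated acid form is the toxic one), biochemical
methane potential (BMP) comparisons between substrate and hydrolysate, and
projection of bench yields to plant scale.

## The stage efficiencies

With DOC_in / DOC_res the ingoing and residual dissolved organic carbon,
TOC_tot the total ingoing organic carbon, TC_gases the CH4 + CO2 carbon per
litre of substrate fed, and TOC_VFA the carbon held in fermentation acids
(all mg C/L):

```
hydrolysis      = (DOC_res + TC_gases - DOC_in) / (TOC_tot - DOC_in) x 100   [% of TOC in]
acidogenesis    = (TOC_VFA + TC_gases) / (DOC_res + TC_gases)        x 100   [% of DOC]
acetogenesis    = TOC_acetate / TOC_VFA                              x 100   [% of VFA C]
protein hydrol. = (1 - RP_hydrolysate / RP_substrate)                x 100   [% of raw protein]
methanogenesis  = CH4_C / TOC_tot                                    x 100   [% of TOC in]
```

where raw protein RP = (Kjeldahl-N − NH4-N) × 6.25, and gas volumes are
normalized to 273.2 K / 1.01325 bar (22.414 L/mol). Acid speciation uses
Henderson–Hasselbalch at a measured pH and Ostwald's dilution law for the
acid alone in water; the two bracket real hydrolysate behaviour and both
are always reported.

Because no public daily reactor dataset accompanies these methods, the
package ships a synthetic generator (`synthetic_truth()`,
`generate_series()`, `generate_bmp()`, `generate_dilution()`) whose ground
truth the full pipeline must recover — exactly in noise-free mode, and to
fractions of a percentage point under realistic measurement noise.

## Worked example

```r
library(adcarbon)

truth <- synthetic_truth(preset = "sludge_co")   # sludge-fed acidic reactor
obs   <- generate_series(truth, n_days = 65, noise_cv = 0.05, seed = 42)
rep   <- stage_report(obs$liquid, obs$gas, truth$schedule)
cat(format_stage_table(rep, digits = 1), sep = "\n")
#> Time period                   0-50 d  50-65 d
#> Hydrolysis                     15.0%    14.8%  of TOC in
#> Acidogenesis                   71.0%    61.4%  of DOC
#> Acetogenesis                   37.1%    39.8%  of VFA
#> Protein hydrolysis             64.3%    58.4%  of raw protein in
#> Methanogenesis (1st stage)      2.0%     2.0%  of TOC in

speciate(20, "acetic", ph = 3.9)
#>   method                undissociated_g_l   alpha    ph
#> 1 henderson-hasselbalch              17.6 0.122    3.9
#> 2 ostwald                            19.9 0.00723  2.62
```

The table reads: in days 0–50 this (synthetic, sludge-like) acid stage
solubilized 15% of the ingoing TOC, converted 71% of the dissolved carbon
to acids-plus-gas, held 37% of the VFA carbon as acetate, hydrolysed about
64% of the feed protein, and lost 2% of the TOC to methane. The speciation
table says that of 20 g/L total acetate at pH 3.9, 17.6 g/L is in the
undissociated (toxic) form by the pH-conditioned route and 19.9 g/L by the
dilution-law route.

Other entry points: `bmp_per_gram()` / `net_methane()` for BMP bottle sets
(with `mass_loss_fraction()` to compensate hydrolysate masses for the gas
already lost in the acid stage), `scale_up()` for plant-scale acetate /
foregone-methane / energy estimates, `dilution_linear_fit()` for
dilution-toxicity checks, and `run_pipeline()` to go from a time-series CSV
to a written report bundle. See `vignette` source in `vignettes/` for the
full methods account.

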