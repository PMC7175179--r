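test_that("noise-free series satisfy daily carbon conservation", {
  for (preset in c("sludge_co", "sludge_ww", "food_waste_co",
                   "food_waste_ww")) {
    tr <- synthetic_truth(preset = preset)
    obs <- generate_series(tr, n_days = 25, noise_cv = 0)
    s <- tr$substrate
    feed <- tr$schedule$working_volume / tr$schedule$periods$hrt[1]
    for (d in c(1, 10, 19)) {
      liq <- obs$liquid[obs$liquid$day == d, ]
      gas <- obs$gas[obs$gas$day == d, ]
      tc <- carbon_in_gas(gas, feed)
      i <- if (d >= tr$schedule$periods$day_start[2]) 2 else 1
      unreleased <- (1 - tr$eta_hydrolysis[i]) * (s$toc_tot - s$doc_in)
      expect_equal(liq$doc_res + tc + unreleased, s$toc_tot,
                   tolerance = 1e-9)
    }
  }
})

test_that("noise-free round trip recovers the generator efficiencies exactly", {
  tr <- simple_truth(eta_h = 0.15, eta_a = 0.70, phi = 0.37, eta_m = 0.02,
                     eta_p = 0.6, noise_cv = 0)
  obs <- generate_series(tr, n_days = 30)
  rep <- stage_report(obs$liquid, obs$gas, tr$schedule)
  expect_equal(rep$hydrolysis_pct, 15, tolerance = 1e-9)
  expect_equal(rep$acidogenesis_pct, 70, tolerance = 1e-9)
  expect_equal(rep$acetogenesis_pct, 37, tolerance = 1e-9)
  expect_equal(rep$methanogenesis_1st_pct, 2, tolerance = 1e-9)
  expect_equal(rep$protein_hydrolysis_pct, 60, tolerance = 1e-9)

  # with lactate present, acidogenesis still matches because it counts
  # lactate carbon, while acetogenesis stays on the lactate-free basis
  tr2 <- simple_truth(lactate_share = 0.3, noise_cv = 0)
  obs2 <- generate_series(tr2, n_days = 30)
  rep2 <- stage_report(obs2$liquid, obs2$gas, tr2$schedule)
  expect_equal(rep2$acidogenesis_pct, 70, tolerance = 1e-9)
  expect_equal(rep2$acetogenesis_pct, 37, tolerance = 1e-9)
  expect_gt(obs2$liquid$lac[1], 0)
})

test_that("zero hydrolysis with zero gas leaves residual DOC at ingoing DOC", {
  tr <- simple_truth(eta_h = 0, eta_a = 0.5, phi = 0.4, eta_m = 0,
                     noise_cv = 0)
  obs <- generate_series(tr, n_days = 10)
  rep <- stage_report(obs$liquid, obs$gas, tr$schedule)
  # f_co2_ferm still routes a little carbon to gas; hydrolysis stays 0
  expect_equal(rep$hydrolysis_pct, 0, tolerance = 1e-9)
  expect_equal(rep$doc_res + rep$tc_gases, tr$substrate$doc_in,
               tolerance = 1e-9)
})

test_that("generation is deterministic in the seed", {
  a <- generate_series(simple_truth(noise_cv = 0.05, seed = 7), n_days = 12)
  b <- generate_series(simple_truth(noise_cv = 0.05, seed = 7), n_days = 12)
  expect_identical(a, b)
  c2 <- generate_series(simple_truth(noise_cv = 0.05, seed = 8), n_days = 12)
  expect_false(identical(a$liquid$ac, c2$liquid$ac))
  # the generator restores the caller's RNG state
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_series(simple_truth(), n_days = 3))
  expect_identical(runif(1), before)
})

test_that("infeasible parameter combinations fail at construction", {
  # huge methane draw exceeds the dissolved pool
  expect_error(simple_truth(eta_h = 0.01, eta_a = 0.9, eta_m = 0.9),
               "infeasible")
  expect_error(
    synthetic_truth(preset = "sludge_co", eta_hydrolysis = 1.5),
    "\\[0, 1\\]")
  expect_error(
    synthetic_truth(preset = "sludge_co", vfa_mix = c(pr = 0.5, bu = 0.2)),
    "sum to 1")
  expect_error(synthetic_truth(preset = "nope"), "unknown preset")
})

test_that("dilution generator spans the linear and toxicity regimes", {
  lin <- generate_dilution(20, noise_sd = 0, n_replicates = 1, seed = 1)
  f <- dilution_linear_fit(lin)
  expect_equal(f$slope, 20, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  tox <- generate_dilution(20, toxicity_amp = 5, noise_sd = 0,
                           n_replicates = 1, seed = 1)
  g <- dilution_linear_fit(tox)
  expect_lt(g$curvature, 0)

  a <- generate_dilution(20, seed = 11)
  b <- generate_dilution(20, seed = 11)
  expect_identical(a, b)
  expect_error(generate_dilution(20, fractions = c(0.5, 0.1, 1)),
               "strictly increasing")
})

test_that("noisy efficiencies concentrate near the truth as days accumulate", {
  tr <- simple_truth(noise_cv = 0.10, seed = 21)
  short <- generate_series(tr, n_days = 5)
  tr_long <- simple_truth(noise_cv = 0.10, seed = 21, day_end = 3000)
  errs <- vapply(c(5, 500), function(nd) {
    obs <- generate_series(tr_long, n_days = nd)
    rep <- stage_report(obs$liquid, obs$gas, tr_long$schedule)
    abs(rep$acidogenesis_pct - 70)
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 1)  # averaging must not degrade the estimate
  expect_lt(errs[2], 1.5)          # ~sqrt(n) shrinkage at n = 500
})
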