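test_that("gas carbon accounting matches mole arithmetic", {
  one_mol <- tibble::tibble(volume_norm = 22.414, ch4_frac = 0.5,
                            co2_frac = 0.5)
  expect_equal(carbon_in_gas(one_mol, 1), 12011)
  h2_only <- tibble::tibble(volume_norm = 5, ch4_frac = 0, co2_frac = 0,
                            h2_frac = 1)
  expect_equal(carbon_in_gas(h2_only, 1), 0)
  mixed <- tibble::tibble(volume_norm = 2.2414, ch4_frac = 0.6,
                          co2_frac = 0.4)
  expect_equal(carbon_in_gas(mixed, 0.6), 2001.83, tolerance = 1e-5)
  # raw triple normalized on the fly
  raw <- tibble::tibble(volume_norm = NA_real_, ch4_frac = 0.5,
                        co2_frac = 0.5, raw_volume = 22.414,
                        raw_temp = 273.2, raw_pressure = 1.01325)
  expect_equal(carbon_in_gas(raw, 1), 12011)
  raw$raw_volume <- NA_real_
  expect_error(carbon_in_gas(raw, 1), "raw")
})

test_that("degree of hydrolysis follows its defining ratio", {
  expect_equal(degree_of_hydrolysis(7000, 825, 5500, 21000), 15)
  expect_equal(degree_of_hydrolysis(5500, 0, 5500, 21000), 0)
  expect_equal(degree_of_hydrolysis(21000, 0, 5500, 21000), 100)
  # negative (net DOC consumption) preserved, not clamped
  expect_lt(degree_of_hydrolysis(4000, 0, 5500, 21000), 0)
  expect_error(degree_of_hydrolysis(1, 1, 200, 100), "exceed")

  # monotone: increasing in doc_res and tc_gases, decreasing in doc_in
  base <- degree_of_hydrolysis(7000, 825, 5500, 21000)
  for (d in c(10, 100, 1000)) {
    expect_gt(degree_of_hydrolysis(7000 + d, 825, 5500, 21000), base)
    expect_gt(degree_of_hydrolysis(7000, 825 + d, 5500, 21000), base)
    expect_lt(degree_of_hydrolysis(7000, 825, 5500 + d, 21000), base)
  }
})

test_that("degree of acidogenesis follows its defining ratio", {
  expect_equal(degree_of_acidogenesis(4000, 500, 6000), 4500 / 6500 * 100)
  expect_equal(degree_of_acidogenesis(0, 0, 123), 0)
  expect_equal(degree_of_acidogenesis(777, 0, 777), 100)
  expect_error(degree_of_acidogenesis(1, 0, 0), "undefined")
})

test_that("acetogenesis is the acetate share of VFA carbon", {
  # oracle: 5*0.40003 / (5*0.40003 + 2*0.48640 + 2*0.54528) * 100
  expect_equal(degree_of_acetogenesis(c(ac = 5, pr = 2, bu = 2)),
               49.22, tolerance = 1e-4)
  expect_equal(degree_of_acetogenesis(c(ac = 3)), 100)
  expect_equal(degree_of_acetogenesis(c(ac = 0, pr = 1)), 0)
  expect_error(degree_of_acetogenesis(c(ac = 0, pr = 0)), "undefined")

  # scale invariance
  v <- c(ac = 5, pr = 2, bu = 2, iv = 0.5)
  for (k in c(0.01, 3, 250)) {
    expect_equal(degree_of_acetogenesis(k * v), degree_of_acetogenesis(v))
  }

  # lactate excluded by default, counted on request
  w <- c(ac = 5, lac = 5)
  expect_equal(degree_of_acetogenesis(w), 100)
  expect_equal(degree_of_acetogenesis(w, include_lactate = TRUE), 50,
               tolerance = 1e-3)
})

test_that("methanogenesis, protein and soluble fractions follow their definitions", {
  expect_equal(degree_of_methanogenesis(0, 21000), 0)
  expect_equal(degree_of_methanogenesis(1470, 21000), 7)
  expect_equal(degree_of_methanogenesis(21000, 21000), 100)

  expect_equal(raw_protein(3000, 600), 15000)
  expect_equal(raw_protein(500, 500), 0)
  expect_equal(raw_protein(1000, 0), 6250)
  expect_error(raw_protein(100, 150), "exceeds")

  s <- mixed_sludge_substrate(kjeldahl_n = 3000, nh4_n = 600)
  expect_equal(protein_hydrolysis(s, 3000, 1800), 50)
  expect_equal(protein_hydrolysis(s, 3000, 600), 0)
  expect_equal(protein_hydrolysis(s, 2400, 2400), 100)

  expect_equal(soluble_fraction(5500, 21000), 26.19, tolerance = 1e-3)
  expect_equal(soluble_fraction(24900, 39000), 63.85, tolerance = 1e-3)
  expect_equal(soluble_fraction(0, 10), 0)
  expect_error(soluble_fraction(11, 10), "doc <= toc")
  expect_equal(soluble_fraction(mixed_sludge_substrate()),
               soluble_fraction(5500, 21000))
})

test_that("total soluble fraction is additive and algebraically consistent", {
  expect_equal(total_soluble_fraction(26, 15), 41)
  expect_equal(total_soluble_fraction(0, 0), 0)

  # identity: soluble_in + hydrolysis * (TOC - DOC)/TOC
  #           == (DOC_res + TC_gases)/TOC * 100 for consistent inputs
  doc_in <- 5500; toc <- 21000; doc_res <- 7000; tc <- 825
  hyd <- degree_of_hydrolysis(doc_res, tc, doc_in, toc)
  sol <- soluble_fraction(doc_in, toc)
  expect_equal(sol + hyd * (toc - doc_in) / toc,
               (doc_res + tc) / toc * 100, tolerance = 1e-10)
})

test_that("acid yield inverts the steady-state VS loading", {
  expect_equal(acid_yield(20.4, olr = 13.5, hrt = 10), 151.1,
               tolerance = 1e-3)
  expect_equal(acid_yield(0, olr = 13.5, hrt = 10), 0)
  expect_equal(acid_yield(5, olr = 23.7, hrt = 3), 70.3, tolerance = 1e-3)
  expect_error(acid_yield(1, olr = 0, hrt = 3), "positive")

  # inverse identity: yield * VS fed per litre reproduces concentration
  for (conc in c(0.5, 5, 20.4)) {
    y <- acid_yield(conc, olr = 13.5, hrt = 10)
    expect_equal(y * (13.5 * 10) / 1000, conc, tolerance = 1e-12)
  }
  # schedule interface
  sch <- reactor_schedule(
    5, data.frame(day_start = 0, day_end = 50, olr = 13.5, hrt = 10),
    food_waste_substrate())
  expect_equal(acid_yield(20.4, sch), acid_yield(20.4, 13.5, 10))
})

test_that("molar ratios use registry molar masses", {
  expect_equal(molar_ratio(25, "acetic", 15, "lactic"),
               (25 / 60.05) / (15 / 90.08), tolerance = 1e-12)
  expect_equal(molar_ratio(25, "acetic", 15, "lactic"), 2.50,
               tolerance = 1e-3)
  expect_equal(molar_ratio(10, "acetic", 30, "lactic"), 0.50,
               tolerance = 1e-2)
  expect_equal(molar_ratio(60.05, "acetic", 90.08, "lactic"), 1)
  expect_error(molar_ratio(1, "acetic", 0, "lactic"), "positive")
})

test_that("additive OLR arithmetic converts DOC dose to VS load", {
  expect_equal(olr_with_additive(13.5, 10700, "glucose", 10), 16.17,
               tolerance = 1e-3)
  expect_equal(olr_with_additive(8.8, 0, "glucose", 10), 8.8)
  # carbon fraction ~0.4: 4000 mg C/kg -> ~10 g glucose/kg -> +1 at HRT 10
  expect_equal(olr_with_additive(0, 4000, "glucose", 10), 1.0,
               tolerance = 1e-3)
})
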