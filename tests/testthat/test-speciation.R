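test_that("Henderson-Hasselbalch partition conserves mass and is monotone in pH", {
  r <- undissociated_hh(20, 3.9, 4.756)
  expect_equal(r$undissociated + r$dissociated, 20, tolerance = 1e-12)
  expect_equal(r$undissociated, hh_bisect(20, 3.9, 4.756),
               tolerance = 1e-8)
  expect_equal(r$undissociated, 17.55, tolerance = 1e-3)
  expect_equal(undissociated_hh(8, 4.756, 4.756)$undissociated, 4)
  expect_equal(undissociated_hh(0, 5, 4.756)$undissociated, 0)

  phs <- seq(1, 12, by = 0.5)
  und <- vapply(phs, function(p) undissociated_hh(20, p, 4.756)$undissociated,
                numeric(1))
  expect_true(all(diff(und) < 0))
  expect_equal(undissociated_hh(20, -20, 4.756)$undissociated, 20,
               tolerance = 1e-10)
  expect_equal(undissociated_hh(20, 20, 4.756)$undissociated, 0,
               tolerance = 1e-10)
})

test_that("Ostwald dilution law agrees with a bisection oracle across the grid", {
  for (c0 in c(1e-4, 1e-3, 1e-2, 0.1, 0.333, 1)) {
    for (ka in c(1e-6, 1e-5, 1.754e-5, 1e-4, 1e-3)) {
      got <- undissociated_ostwald(c0, ka)
      expect_equal(got$alpha, ostwald_bisect(c0, ka), tolerance = 1e-10)
      expect_equal(got$undissociated_mol_l, (1 - got$alpha) * c0)
    }
  }
  # worked example: 0.333 mol/L acetate
  ex <- undissociated_ostwald(0.333, 1.754e-5)
  expect_equal(ex$alpha, 0.00723, tolerance = 1e-3)
  expect_equal(ex$undissociated_mol_l * 60.05, 19.86, tolerance = 1e-3)
  # alpha -> 0 as c grows
  expect_lt(undissociated_ostwald(100, 1.754e-5)$alpha,
            undissociated_ostwald(1, 1.754e-5)$alpha)
  # Ka = c gives the golden-ratio conjugate
  expect_equal(undissociated_ostwald(0.02, 0.02)$alpha, (sqrt(5) - 1) / 2,
               tolerance = 1e-12)
  expect_error(undissociated_ostwald(0, 1e-5), "positive")
})

test_that("the two speciation routes agree at the Ostwald-implied pH", {
  for (c0 in c(0.01, 0.1, 0.333)) {
    ka <- 10^-4.756
    ost <- undissociated_ostwald(c0, ka)
    hh <- undissociated_hh(c0, ost$implied_ph, 4.756)
    expect_equal(hh$undissociated, ost$undissociated_mol_l,
                 tolerance = 1e-8)
  }
})

test_that("speciate reports both routes in g/L with their pH", {
  out <- speciate(20, "acetic", ph = 3.9)
  expect_equal(nrow(out), 2)
  hh <- out[out$method == "henderson-hasselbalch", ]
  ost <- out[out$method == "ostwald", ]
  expect_equal(hh$undissociated_g_l, 17.55, tolerance = 1e-3)
  expect_equal(ost$undissociated_g_l, 19.86, tolerance = 1e-3)
  # the two routes bracket intermediate mixture behaviour
  expect_true(hh$undissociated_g_l < ost$undissociated_g_l)
  expect_error(speciate(20, "acetic", method = "hh"), "needs a measured pH")
  expect_error(speciate(20, "glucose", ph = 7), "no pKa")
})

test_that("confidence intervals use the Student t quantile", {
  r <- confidence_interval(c(5, 5, 5))
  expect_equal(r$mean, 5)
  expect_equal(r$half_width, 0)
  r2 <- confidence_interval(c(1, 2, 3))
  expect_equal(r2$mean, 2)
  expect_equal(r2$half_width, qt(0.975, 2) * 1 / sqrt(3))
  expect_equal(r2$half_width, 2.484, tolerance = 1e-3)
  expect_error(confidence_interval(5), "at least 2")
})

test_that("dilution fits recover exact lines and flag degenerate series", {
  exact <- tibble::tibble(fraction = c(0.1, 0.5, 0.75, 0.9, 1),
                          acetate_after = 20 * c(0.1, 0.5, 0.75, 0.9, 1))
  f <- dilution_linear_fit(exact)
  expect_equal(f$slope, 20, tolerance = 1e-10)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_false(f$toxicity_release)

  const <- tibble::tibble(fraction = c(0.1, 0.5, 1),
                          acetate_after = c(7, 7, 7))
  g <- dilution_linear_fit(const)
  expect_true(g$degenerate)
  expect_true(is.na(g$r_squared))

  expect_error(dilution_linear_fit(exact[1:2, ]), "3 distinct")
})
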