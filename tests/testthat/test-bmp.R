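make_set <- function(sample_extra, days = 0:10, blank_amp = 6,
                     inoc_vs = 0.9, sub_mass = 2, sub_vs = 0.3) {
  blank <- blank_amp * (1 - exp(-0.2 * days))   # per bottle, inoc_vs g VS
  bottles <- tibble::tibble(
    label = c("s1", "b1", "b2"),
    role = c("sample", "blank", "blank"),
    substrate_mass_g = c(sub_mass, 0, 0),
    substrate_vs_g = c(sub_vs, 0, 0),
    inoculum_vs_g = inoc_vs)
  curves <- dplyr::bind_rows(
    tibble::tibble(label = "s1", day = days, ml_ch4 = blank + sample_extra),
    tibble::tibble(label = "b1", day = days, ml_ch4 = blank),
    tibble::tibble(label = "b2", day = days, ml_ch4 = blank))
  bmp_set(bottles, curves)
}

test_that("blank correction recovers a known added curve exactly", {
  days <- 0:10
  known <- 15 * (1 - exp(-0.5 * days))
  set <- make_set(known, days)
  net <- net_methane(set, "s1")
  expect_equal(net$ml_ch4_net, known, tolerance = 1e-9)

  # a blank against its own cohort is ~0
  net_b <- net_methane(set, "b1")
  expect_equal(net_b$ml_ch4_net, rep(0, length(days)), tolerance = 1e-9)

  # zero inoculum: nothing subtracted
  set0 <- set
  set0$bottles$inoculum_vs_g[set0$bottles$label == "s1"] <- 0
  expect_equal(net_methane(set0, "s1")$ml_ch4_net,
               set0$curves$ml_ch4[set0$curves$label == "s1"])

  # additivity: net of (sample + extra) = net of sample + extra
  extra <- 3 * (1 - exp(-0.3 * days))
  set2 <- make_set(known + extra, days)
  expect_equal(net_methane(set2, "s1")$ml_ch4_net,
               net$ml_ch4_net + extra, tolerance = 1e-9)

  # misaligned day grids are refused
  bad <- set
  bad$curves$day[bad$curves$label == "b1"] <-
    bad$curves$day[bad$curves$label == "b1"] + 0.5
  expect_error(net_methane(bad, "s1"), "day grids differ")
})

test_that("per-gram potential inverts the plateau and compensates mass loss", {
  days <- 0:15
  known <- 15 * (1 - exp(-0.5 * days))  # plateau ~15 mL
  set <- make_set(known, days, sub_vs = 0.3, sub_mass = 2)
  r_vs <- bmp_per_gram(set, basis = "vs")
  plateau <- max(net_methane(set, "s1")$ml_ch4_net)
  expect_equal(r_vs$mean * 0.3, plateau, tolerance = 1e-9)
  r_mat <- bmp_per_gram(set, basis = "material")
  expect_equal(r_mat$mean * 2, plateau, tolerance = 1e-9)

  # compensation: identity at zero loss, monotone decreasing in the loss
  r0 <- bmp_per_gram(set, basis = "material", as_fed = TRUE,
                     mass_loss_fraction = 0)
  expect_equal(r0$mean, r_mat$mean)
  prev <- r_mat$mean
  for (mlf in c(0.02, 0.05, 0.1)) {
    ri <- bmp_per_gram(set, basis = "material", as_fed = TRUE,
                       mass_loss_fraction = mlf)
    expect_lt(ri$mean, prev)
    prev <- ri$mean
  }
  expect_error(bmp_per_gram(set, basis = "material", as_fed = TRUE),
               "mass-loss")
})

test_that("mass-loss fraction follows gas-mass stoichiometry", {
  # 1 mol CH4 + 1 mol CO2 per litre fed: 16.043 + 44.009 g over 1000 g
  expect_equal(mass_loss_fraction(12011, 12011),
               (16.043 + 44.009) / 1000, tolerance = 1e-9)
  expect_equal(mass_loss_fraction(0, 0), 0)
  expect_warning(mass_loss_fraction(6e4, 6e4), "plausible")
})

test_that("second-stage methanogenesis converts methane volume to TOC share", {
  sub <- substrate_characterization("x", 0.1, 0.9, 1000, 24022)
  # 22.414 mL/g * 1000 g/L = 1 mol CH4/L = 12011 mg C -> 50%
  expect_equal(methanogenesis_2nd_stage(22.414, sub), 50, tolerance = 1e-9)
  expect_equal(methanogenesis_2nd_stage(0, sub), 0)
})

test_that("kinetic summaries match closed forms", {
  days <- 0:20
  curve <- tibble::tibble(day = days, ml_ch4 = 100 * (1 - exp(-0.5 * days)))
  ks <- kinetic_summary(curve)
  expect_equal(ks$plateau, max(curve$ml_ch4))
  # t50 of the sampled curve interpolates near ln(2)/k
  expect_equal(ks$t50, log(2) / 0.5, tolerance = 0.05)

  ramp <- tibble::tibble(day = 0:10, ml_ch4 = seq(0, 100, by = 10))
  expect_equal(kinetic_summary(ramp)$t50, 5)
  expect_equal(kinetic_summary(ramp)$initial_rate, 10)

  flat <- tibble::tibble(day = 0:5, ml_ch4 = 0)
  expect_true(is.na(kinetic_summary(flat)$t50))
  expect_equal(kinetic_summary(flat)$plateau, 0)

  wiggly <- tibble::tibble(day = 0:3, ml_ch4 = c(0, 5, 4, 8))
  expect_warning(ks2 <- kinetic_summary(wiggly), "non-monotone")
  expect_equal(ks2$plateau, 8)
})

test_that("synthetic BMP bottles recover the generator truth", {
  # noise-free: plateau tolerance is exactly the unfinished tail e^(-15k)
  set0 <- generate_bmp(true_bmp = 50, k = 0.3, noise_cv = 0, seed = 1)
  r0 <- bmp_per_gram(set0, basis = "vs")
  expect_equal(r0$mean, 50 * (1 - exp(-0.3 * 15)), tolerance = 1e-9)

  # zero substrate potential: sample indistinguishable from blank
  setz <- generate_bmp(true_bmp = 0, k = 0.3, noise_cv = 0, seed = 1)
  expect_equal(max(abs(net_methane(setz, "sample_1")$ml_ch4_net)), 0,
               tolerance = 1e-9)

  # seed determinism
  a <- generate_bmp(50, seed = 42)
  b <- generate_bmp(50, seed = 42)
  expect_identical(a$curves, b$curves)
  c2 <- generate_bmp(50, seed = 43)
  expect_false(identical(a$curves, c2$curves))
})

test_that("bmp csv round trip preserves the set", {
  set <- generate_bmp(50, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bmp_csv(set, path)
  back <- read_bmp_csv(path)
  expect_equal(as.data.frame(back$bottles), as.data.frame(set$bottles))
  expect_equal(back$curves$ml_ch4, set$curves$ml_ch4, tolerance = 1e-12)
})
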