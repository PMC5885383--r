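test_that("isotope dilution recovers a constructed body water exactly", {
  d <- default_dose("18O")
  # invert the dilution equation so TBW is 2500 mol, then evaluate forward
  target <- 2500
  grad <- d$grams / d$mw_dose * d$ape_percent / 100 * 18.02 /
    (d$r_standard * 1.01 * target)
  tbw <- compute_tbw(d, e_final = 0.5 + grad, e_predose = 0.5)
  expect_equal(tbw$tbw_mol, target, tolerance = 1e-9)
  expect_equal(tbw$tbw_kg, target * 18.02 / 1000, tolerance = 1e-9)

  # linear in dose mass
  d2 <- isotope_dose(2 * d$grams, d$mw_dose, d$ape_percent, "18O")
  expect_equal(compute_tbw(d2, 0.5 + grad, 0.5)$tbw_mol, 2 * target,
               tolerance = 1e-9)
})

test_that("degenerate dilution gradients are rejected", {
  d <- default_dose("18O")
  expect_error(compute_tbw(d, 0.4, 0.4), "dilution undefined")
  expect_error(compute_tbw(d, 0.3, 0.4), "inconsistent enrichments")
})

test_that("deuterium dilution space option changes only the divisor", {
  d <- isotope_dose(12, 20.03, 99.9, "2H")
  a <- compute_tbw(d, 1e-3, 0)$tbw_mol
  b <- compute_tbw(d, 1e-3, 0, deuterium_space = TRUE)$tbw_mol
  expect_equal(a / b, 1.04 / 1.01, tolerance = 1e-12)
})

test_that("elimination-rate fits match exact and oracle values", {
  # exact mono-exponential: k recovered exactly
  s <- urine_series("p1", "18O", 0:10, 100 * exp(-0.1 * 0:10))
  expect_equal(fit_elimination_rate(s)$k, 0.1, tolerance = 1e-12)
  # constant enrichment above baseline: no elimination
  s0 <- urine_series("p1", "2H", c(0, 2, 5), rep(7, 3), baseline = 2)
  expect_equal(fit_elimination_rate(s0)$k, 0, tolerance = 1e-12)
  # noisy series agrees with the explicit-summation oracle
  set.seed(101)
  for (rep in 1:20) {
    t <- sort(runif(8, 0, 10))
    e <- 50 * exp(-0.12 * t) * exp(rnorm(8, 0, 0.05)) + 1
    s <- urine_series("p", "18O", t, e, baseline = 1)
    expect_equal(fit_elimination_rate(s)$k, oracle_k(t, e, 1),
                 tolerance = 1e-10)
  }
})

test_that("samples at or below baseline are dropped, with a floor of two", {
  s <- urine_series("p1", "18O", c(0, 1, 2, 3), c(10, 6, 2, 1.5),
                    baseline = 2)
  expect_warning(f <- fit_elimination_rate(s), "dropped 2")
  expect_identical(f$n_used, 2L)
  s2 <- urine_series("p1", "18O", c(0, 1, 2), c(10, 2, 1), baseline = 2)
  expect_warning(expect_error(fit_elimination_rate(s2), "fewer than 2"))
})

test_that("Schoeller CO2 production matches hand substitution and scales in N", {
  # N = 2220, kO = 0.12, kH = 0.09:
  # 2220 x 0.0276 x (1/2.078 - 0.0246 x 1.05) = 27.9034...
  hand <- 2220 * (1.01 * 0.12 - 1.04 * 0.09) * (1 / 2.078 - 0.0246 * 1.05)
  out <- compute_rco2(2220, 0.12, 0.09)
  expect_equal(out$rco2_mol_d, hand, tolerance = 1e-12)
  expect_equal(hand, 27.9, tolerance = 0.01)
  expect_equal(out$rh2of_mol_d, 1.05 * 2220 * 0.0276, tolerance = 1e-9)

  # zero turnover
  z <- compute_rco2(2220, 0, 0)
  expect_identical(z$rco2_mol_d, 0)
  expect_identical(z$rh2of_mol_d, 0)

  # linearity in N (property over a grid)
  for (n in c(1500, 2000, 3000)) for (c in c(2, 5)) {
    expect_equal(compute_rco2(c * n, 0.11, 0.08)$rco2_mol_d,
                 c * compute_rco2(n, 0.11, 0.08)$rco2_mol_d,
                 tolerance = 1e-12)
  }

  # 1.01 kO < 1.04 kH is flagged, not clipped
  expect_warning(neg <- compute_rco2(2220, 0.08, 0.09), "negative")
  expect_true(neg$negative)
  expect_lt(neg$rco2_mol_d, 0)
})

test_that("energy equivalent of CO2 follows the Weir constant", {
  expect_equal(co2_energy_equivalent(0.86), 22.414 * (1.106 + 3.941 / 0.86),
               tolerance = 1e-12)
  expect_equal(co2_energy_equivalent(0.86), 127.5, tolerance = 0.01)
  expect_identical(energy_from_rco2(0), 0)
  expect_equal(energy_from_rco2(35), 35 * co2_energy_equivalent(0.86),
               tolerance = 1e-12)
  # strictly decreasing in RQ at fixed production
  rqs <- seq(0.7, 1.0, by = 0.05)
  expect_true(all(diff(energy_from_rco2(30, rqs)) < 0))
  expect_error(energy_from_rco2(30, rq = 1.2), "physiologic")
  expect_error(energy_from_rco2(-1), "rco2")
})

test_that("full DLW chain is faithful to a noiseless forward model", {
  # grid round trip: body water 30-55 kg, production 15-45 mol/d
  for (tbw in seq(30, 55, by = 5)) for (rco2 in seq(15, 45, by = 10)) {
    cfg <- sim_config(list(), seed = 5, sampling_times = 0:7)
    s <- generate_isotope_series(tbw, rco2, cfg)
    res <- compute_ee_dlw(s$o18, s$h2)
    expect_lt(abs(res$tdee - energy_from_rco2(rco2)) /
                energy_from_rco2(rco2), 1e-3)
  }
})

test_that("the composed pipeline equals an independent end-to-end script", {
  cfg <- sim_config(list(), seed = 77, isotope_noise_cv = 0.02,
                    sampling_times = 0:7)
  s <- generate_isotope_series(42, 33, cfg)
  res <- compute_ee_dlw(s$o18, s$h2)

  # independent recomputation from the raw series, explicit sums throughout
  d <- default_dose("18O")
  ko <- oracle_k(s$o18$time_d, s$o18$enrichment, s$o18$baseline)
  kh <- oracle_k(s$h2$time_d, s$h2$enrichment, s$h2$baseline)
  b <- oracle_ls(s$o18$time_d, log(s$o18$enrichment - s$o18$baseline))
  e0 <- exp(b[["intercept"]])
  n_mol <- d$grams / d$mw_dose * d$ape_percent / 100 * 18.02 /
    (d$r_standard * e0) / 1.01
  flux <- 1.01 * ko - 1.04 * kh
  rco2 <- n_mol / 2.078 * flux - 0.0246 * 1.05 * n_mol * flux
  tdee <- rco2 * 22.414 * (1.106 + 3.941 / 0.86)
  expect_equal(res$tdee, tdee, tolerance = 1e-8)
})

test_that("a missing or mislabeled isotope is reported by name", {
  cfg <- sim_config(list(), seed = 5, sampling_times = 0:7)
  s <- generate_isotope_series(40, 30, cfg)
  expect_error(compute_ee_dlw(s$h2, s$h2), "18O")
  expect_error(compute_ee_dlw(s$o18, s$o18), "2H")
})
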