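test_that("quartile scheme derivation uses linear-interpolation quantiles", {
  s <- derive_paf_scheme(c(1, 2, 3, 4))
  expect_equal(s$cutpoints, c(1.75, 2.5, 3.25), tolerance = 1e-12)
  expect_error(derive_paf_scheme(rep(2, 10)), "degenerate")
  # structural property: always exactly three ascending cutpoints
  set.seed(55)
  for (i in 1:20) {
    s <- derive_paf_scheme(runif(12, 1.5, 3.5))
    expect_length(s$cutpoints, 3)
    expect_true(all(diff(s$cutpoints) > 0))
  }
})

test_that("factor assignment reproduces the published course grouping", {
  expect_identical(assign_paf(2.61), 2L)   # Combat Dive School
  expect_identical(assign_paf(3.05), 3L)   # Urban Combat
  expect_identical(assign_paf(1.97), 0L)   # Weapons Training
  expect_identical(assign_paf(2.31), 1L)   # Platoon Raids
  # boundary values fall in the lower band
  expect_identical(assign_paf(c(2.10, 2.40, 2.75)), c(0L, 1L, 2L))
  # all 12 published course PALs land in their published quartile
  en <- sof_training_energy()
  expect_identical(assign_paf(en$pal), as.integer(en$paf))
})

test_that("published model coefficients predict printed course means", {
  expect_equal(round(predict_model_a(80.8, 3)), 5528)   # Urban Combat
  expect_equal(round(predict_model_a(76.4, 2)), 4610)   # RASP
  expect_equal(round(predict_model_a(79.67, 2)), 4767)  # Squad Raids
  expect_equal(round(predict_model_b(67.9, 2)), 4921)   # Squad Raids
  expect_equal(predict_model_b(69.3, 0), 3574.607, tolerance = 1e-3)
  # intercepts
  expect_equal(predict_energy(published_model("A"), 1e-9, 0), -467.22,
               tolerance = 1e-6)
  # fixed slope step per PAF unit
  expect_equal(predict_model_b(69.3, 1) - predict_model_b(69.3, 0), 716.49,
               tolerance = 1e-12)
  expect_warning(predict_model_a(80, 5), "paf")
})

test_that("predictions are affine: mean of predictions = prediction at means", {
  set.seed(66)
  bm <- rnorm(40, 82, 8)
  paf <- sample(0:3, 40, replace = TRUE)
  m <- published_model("A")
  expect_equal(mean(predict_energy(m, bm, paf)),
               predict_energy(m, mean(bm), mean(paf)), tolerance = 1e-10)
})

test_that("model fitting interpolates exact data and matches the oracle", {
  co <- toy_cohort()
  truth <- published_model("A")
  co$tdee_kcal_d <- predict_energy(truth, co$body_mass_kg, co$paf)
  fit <- fit_prediction_model(co, "body_mass")
  expect_equal(fit$intercept, truth$intercept, tolerance = 1e-8)
  expect_equal(fit$beta_mass, truth$beta_mass, tolerance = 1e-8)
  expect_equal(fit$beta_paf, truth$beta_paf, tolerance = 1e-8)
  expect_equal(fit$see, 0, tolerance = 1e-8)

  set.seed(77)
  co$tdee_kcal_d <- co$tdee_kcal_d + rnorm(nrow(co), 0, 300)
  fit <- fit_prediction_model(co, "body_mass")
  o <- oracle_ols3(co$tdee_kcal_d, co$body_mass_kg, co$paf)
  expect_equal(c(fit$intercept, fit$beta_mass, fit$beta_paf), o,
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  co <- toy_cohort()
  co$paf <- 1L
  expect_error(fit_prediction_model(co, "body_mass"), "singular")
  expect_error(fit_prediction_model(toy_cohort()[1:3, ], "ffm"),
               "at least 4")
})

test_that("refits on simulated cohorts recover the published coefficients", {
  # bias shrinks as n grows (parameter recovery at three sizes)
  truth <- published_model("B")
  sizes <- c(50, 133, 500)
  err <- vapply(seq_along(sizes), function(i) {
    n_per <- ceiling(sizes[i] / 4)
    specs <- lapply(0:3, function(pf)
      course_spec(paste0("c", pf), n_per, 82, 6, 67, 5, 4500, 500,
                  paf = pf))
    reps <- vapply(1:40, function(r) {
      cfg <- sim_config(specs, seed = 5000 + 100 * i + r,
                        model_truth = truth, residual_sd = 500)
      f <- fit_prediction_model(generate_cohort(cfg), "ffm")
      abs(f$beta_mass - truth$beta_mass)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_lt(err[3], err[1])  # slope error shrinks with n
  expect_lt(err[3], 0.1 * abs(truth$beta_mass))
})

test_that("model evaluation flags nothing when predictions are perfect", {
  co <- toy_cohort()
  m <- published_model("A")
  co$tdee_kcal_d <- predict_energy(m, co$body_mass_kg, co$paf)
  ev <- evaluate_model(co, m)
  expect_equal(ev$r, 1, tolerance = 1e-12)
  expect_equal(ev$see, 0, tolerance = 1e-9)
  expect_true(all(ev$by_course$p_bonferroni >= 0.05))
})

test_that("per-course differences and Bonferroni match a hand oracle", {
  co <- toy_cohort()
  m <- published_model("A")
  ev <- evaluate_model(co, m)
  pred <- predict_energy(m, co$body_mass_kg, co$paf)
  err <- pred - co$tdee_kcal_d
  for (g in unique(co$course)) {
    i <- co$course == g
    row <- ev$by_course[ev$by_course$course == g, ]
    expect_equal(row$mean_diff, mean(err[i]), tolerance = 1e-10)
    # one-sample t-test by explicit formula
    tt <- mean(err[i]) / (sd(err[i]) / sqrt(sum(i)))
    p <- 2 * pt(-abs(tt), sum(i) - 1)
    expect_equal(row$p, p, tolerance = 1e-10)
    expect_equal(row$p_bonferroni, min(1, 3 * p), tolerance = 1e-10)
  }
  expect_identical(ev$m_tests, 3L)
})

test_that("singleton courses are excluded from testing with a warning", {
  co <- rbind(toy_cohort(),
              data.frame(id = "P10", course = "delta", body_mass_kg = 85,
                         ffm_kg = 68, tdee_kcal_d = 4600,
                         intake_kcal_d = 3000, paf = 2L))
  expect_warning(ev <- evaluate_model(co, published_model("A")), "delta")
  expect_true(is.na(ev$by_course$p[ev$by_course$course == "delta"]))
  expect_identical(ev$m_tests, 3L)
})

test_that("model coefficients round-trip through their JSON file", {
  m <- fit_prediction_model(toy_cohort(), "ffm")
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$intercept, m$intercept, tolerance = 1e-12)
  expect_equal(m2$beta_mass, m$beta_mass, tolerance = 1e-12)
  expect_equal(m2$beta_paf, m$beta_paf, tolerance = 1e-12)
  expect_identical(m2$mass_kind, m$mass_kind)
})
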