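test_that("rat simulation is exactly reproducible under a fixed seed", {
  a <- simulate_rat(rat_preset("wistar"), n_subjects = 3, seed = 11)
  b <- simulate_rat(rat_preset("wistar"), n_subjects = 3, seed = 11)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$residuals, b$residuals)
  c <- simulate_rat(rat_preset("wistar"), n_subjects = 3, seed = 12)
  expect_false(identical(a$profiles, c$profiles))
})

test_that("noise-free simulation equals the closed forms exactly", {
  st <- simulate_rat(rat_preset("gk"), n_subjects = 2, error_cv = 0,
                     iiv_cv = 0, seed = 5)
  p <- rat_preset("gk")
  iv <- dplyr::filter(st$profiles, route == "iv_bolus", subject_id == "gk_01")
  expect_equal(iv$conc_ng_ml,
               iv_bolus_concentration(iv$time_hr, p$iv_dose, p$k_e, p$Vd_ss),
               tolerance = 1e-12)
  td <- dplyr::filter(st$profiles, route == "transdermal",
                      subject_id == "gk_01")
  expect_equal(td$conc_ng_ml,
               bateman_concentration(td$time_hr, p$td_dose, p$F, p$k_a,
                                     p$k_e, p$Vd_ss * td$body_weight_kg[1]),
               tolerance = 1e-12)
  # body weight still varies between animals; PK parameters do not
  expect_equal(st$subjects$k_a, rep(p$k_a, 2))
})

test_that("between-animal draws are mean-preserving at large n", {
  st <- simulate_rat(rat_preset("gk"), n_subjects = 1000, error_cv = 0.10,
                     iiv_cv = 0.15, seed = 21)
  expect_equal(mean(st$subjects$k_a), 3.17e-2, tolerance = 0.02)
  expect_equal(sd(st$subjects$k_a) / mean(st$subjects$k_a), 0.15,
               tolerance = 0.1)
})

test_that("patch residuals encode the release fraction with assay noise", {
  st <- simulate_rat(rat_preset("wistar"), n_subjects = 200, seed = 31)
  fa <- release_ratio(st$residuals$x_unused_ug, st$residuals$x_used_ug)
  expect_true(all(fa >= 0 & fa <= 1))
  expect_equal(mean(fa), rat_preset("wistar")$F_a, tolerance = 0.02)
})

test_that("simulation rejects invalid noise settings and missing seeds", {
  expect_error(simulate_rat(rat_preset("gk"), 2, error_cv = -0.1, seed = 1),
               "negative")
  expect_error(simulate_rat(rat_preset("gk"), 2), "seed")
  expect_error(simulate_cohort(cohort_preset()), "seed")
})

test_that("cohort simulation is reproducible and round-trips the rule", {
  a <- simulate_cohort(cohort_preset(n = 200), seed = 8)
  b <- simulate_cohort(cohort_preset(n = 200), seed = 8)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$records, b$records)
  # constructive guarantee: extraction returns exactly the generated period
  out <- titration_period(a$records)
  joined <- dplyr::inner_join(out, a$truth, by = "patient_id")
  expect_identical(joined$titration_period, joined$period)
  expect_false(any(joined$censored))
  # and brute force agrees record by record
  expected <- vapply(split(a$records, a$records$patient_id), function(r) {
    brute_titration(r$dose_mg[order(r$day)], r$rescue_count[order(r$day)])
  }, integer(1))
  expect_identical(expected[joined$patient_id],
                   setNames(joined$period, joined$patient_id))
})

test_that("cohort marginals match the preset at large n", {
  cs <- simulate_cohort(cohort_preset(n = 10000), seed = 13)
  expect_equal(median(cs$cohort$age), 66, tolerance = 0.02)
  expect_equal(median(cs$cohort$bmi), 20.3, tolerance = 0.02)
  expect_equal(unname(quantile(cs$cohort$age, 0.25)), 58, tolerance = 0.03)
  expect_equal(mean(cs$cohort$female), 1 - 0.618, tolerance = 0.05)
  expect_equal(mean(is.na(cs$cohort$albumin)), 34 / 387, tolerance = 0.15)
  expect_equal(mean(cs$cohort$E14), 0.171, tolerance = 0.05)
  # outcome fraction tracks the calibrated target
  expect_equal(mean(cs$truth$outcome), 126 / 387, tolerance = 0.05)
  # periods live in the observed range, with a right-skewed long tail
  expect_true(all(cs$truth$period >= 5 & cs$truth$period <= 39))
  longs <- cs$truth$period[cs$truth$outcome == 1]
  expect_gt(mean(longs <= 12), 0.5)
})

test_that("a null outcome model gives a half/half split", {
  p <- cohort_preset(n = 4000)
  p$outcome_log_odds[] <- 0
  p$target_outcome_fraction <- 0.5
  cs <- simulate_cohort(p, seed = 17)
  expect_equal(mean(cs$truth$outcome), 0.5, tolerance = 0.05)
})

test_that("outcome depends only on coefficient-bearing factors", {
  # E11 and I10 carry zero log-odds: their association with the outcome is
  # null in a large cohort
  cs <- simulate_cohort(cohort_preset(n = 10000), seed = 19)
  dat <- dplyr::mutate(cs$cohort, y = cs$truth$outcome)
  res <- univariate_screen(dat, outcome = "y", factors = c("E11", "I10"))
  expect_true(all(abs(log(res$OR)) < 0.35))
  # while a strong true factor is readily detected
  res_dm <- univariate_screen(dat, outcome = "y", factors = "E14")
  expect_lt(res_dm$p_value, 1e-4)
  expect_lt(res_dm$OR, 1)
})

test_that("near-degenerate prevalence triggers a warning", {
  p <- cohort_preset(n = 50)
  expect_warning(simulate_cohort(p, seed = 23), "Near-degenerate")
})

test_that("presets round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_preset(cohort_preset(), path)
  back <- read_preset(path)
  orig <- cohort_preset()
  expect_equal(back$comorbidity_prevalence, orig$comorbidity_prevalence)
  expect_equal(back$outcome_log_odds, orig$outcome_log_odds)
  expect_equal(back$age, orig$age)

  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_preset(rat_preset("gk"), path2)
  expect_equal(read_preset(path2)$k_a, 3.17e-2)
})
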