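test_that("IV bolus curve has the closed-form origin, decay and area", {
  # C0 forced by dose over volume (Wistar-scale values)
  expect_equal(iv_bolus_concentration(0, dose = 10, k_e = 0.279, Vd = 6.49),
               10 / 6.49, tolerance = 1e-12)
  # vanishes at long times
  expect_lt(iv_bolus_concentration(1e4, 10, 0.279, 6.49), 1e-12)
  # quadrature area matches dose / (k_e * Vd) to < 0.1%
  auc_num <- quad_auc(function(t) iv_bolus_concentration(t, 10, 0.279, 6.49),
                      upper = 300)
  expect_equal(auc_num, 10 / (0.279 * 6.49), tolerance = 1e-3)
})

test_that("model equations reject non-positive parameters and times", {
  expect_error(iv_bolus_concentration(1, dose = -1, k_e = 0.2, Vd = 6),
               "positive")
  expect_error(iv_bolus_concentration(-1, dose = 1, k_e = 0.2, Vd = 6),
               "non-negative")
  expect_error(bateman_concentration(1, 160, F_bio = 1.2, 0.02, 0.2, 2),
               "F_bio")
  expect_error(bateman_concentration(1, 160, 0.5, k_a = 0, k_e = 0.2, Vd = 2),
               "positive")
})

test_that("Bateman curve starts at zero and peaks at the analytic argmax", {
  expect_equal(bateman_concentration(0, 160, 0.53, 0.0228, 0.279, 2), 0)

  # analytic argmax against a fine grid search, Wistar-mean rates
  k_a <- 0.0228; k_e <- 0.279
  tt <- seq(0.01, 60, by = 0.001)
  cc <- bateman_concentration(tt, 160, 0.53, k_a, k_e, 6.49 * 0.305)
  t_grid <- tt[which.max(cc)]
  t_analytic <- bateman_tmax(k_a, k_e)
  expect_equal(t_grid, t_analytic, tolerance = 1e-3)
  # consistent with the observed transdermal peak time around 9.6 hr
  expect_equal(t_analytic, 9.775, tolerance = 1e-3)
})

test_that("k_a = k_e degeneracy routes to the limit form continuously", {
  k <- 0.1
  t <- c(0.5, 5, 20)
  exact_limit <- 160 * 0.5 * k * t * exp(-k * t) / 2
  expect_equal(bateman_concentration(t, 160, 0.5, k, k, 2), exact_limit,
               tolerance = 1e-12)
  # just outside the switch threshold the general form agrees closely
  near <- bateman_concentration(t, 160, 0.5, k * (1 + 1e-7), k, 2)
  expect_equal(near, exact_limit, tolerance = 1e-6)
  expect_false(any(is.nan(near)))
})

test_that("Bateman curves are non-negative and conserve the absorbable area", {
  set.seed(71)
  for (i in 1:25) {
    k_a <- runif(1, 0.005, 2); k_e <- runif(1, 0.005, 2)
    F_bio <- runif(1, 0.1, 1); Vd <- runif(1, 0.5, 10)
    tt <- seq(0, 12 / min(k_a, k_e), length.out = 400)
    cc <- bateman_concentration(tt, 160, F_bio, k_a, k_e, Vd)
    expect_true(all(cc >= 0))
    auc_num <- quad_auc(function(t) bateman_concentration(t, 160, F_bio,
                                                          k_a, k_e, Vd),
                        upper = 60 / min(k_a, k_e))
    expect_equal(auc_num, 160 * F_bio / (k_e * Vd), tolerance = 1e-3)
  }
})

test_that("full-depot curve is symmetric under rate swap with volume rescale", {
  t <- c(1, 5, 20, 80)
  a <- bateman_concentration(t, 160, 0.5, 0.0228, 0.279, Vd = 2)
  b <- bateman_concentration(t, 160, 0.5, 0.279, 0.0228,
                             Vd = 2 * 0.279 / 0.0228)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("terminal slope of the flip-flop curve equals the slower rate", {
  k_a <- 0.0228; k_e <- 0.279
  k_min <- min(k_a, k_e)
  tt <- seq(5 / k_min, 10 / k_min, length.out = 50)
  cc <- bateman_concentration(tt, 160, 0.53, k_a, k_e, 2)
  slope <- -coef(lm(log(cc) ~ tt))[[2]]
  expect_equal(slope, k_min, tolerance = 1e-4)
})

test_that("truncated-input dialect decays at k_e after patch removal", {
  k_a <- 0.0317; k_e <- 0.255; Vd <- 6.94 * 0.339
  c24 <- bateman_concentration(24, 160, 0.555, k_a, k_e, Vd)
  c30 <- bateman_concentration(30, 160, 0.555, k_a, k_e, Vd,
                               removal_time = 24, dialect = "truncated_input")
  expect_equal(c30, c24 * exp(-k_e * 6), tolerance = 1e-12)
  # before removal both dialects agree
  expect_equal(
    bateman_concentration(12, 160, 0.555, k_a, k_e, Vd,
                          removal_time = 24, dialect = "truncated_input"),
    bateman_concentration(12, 160, 0.555, k_a, k_e, Vd))
  # full-depot ignores removal entirely
  expect_equal(
    bateman_concentration(30, 160, 0.555, k_a, k_e, Vd, removal_time = 24),
    bateman_concentration(30, 160, 0.555, k_a, k_e, Vd))
})

test_that("parameter validation enforces positivity and rate consistency", {
  expect_silent(validate_pk_parameters(
    list(k_e = 0.26, CL_tot = 1.77, Vd_ss = 6.94, F = 0.55)))
  expect_error(validate_pk_parameters(
    list(k_e = 0.5, CL_tot = 1.77, Vd_ss = 6.94)), "deviates")
  expect_error(validate_pk_parameters(list(k_e = -1)), "positive")
  expect_error(validate_pk_parameters(list(F = 1.2)), "F")
})
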