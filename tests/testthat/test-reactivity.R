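test_that("the F term reproduces its hand-computed value", {
  # chi_M = 2 eV, S = 0.5 1/eV, sigma = 3.075:
  # inner = 2*(0.5 + 30.75/3.075) + 0.03822/3.075 = 21.012429...
  F <- f_term(chi_M = 2, S_global = 0.5, s2_plus = 1.5, s5_plus = 1.575)
  expect_equal(F, 1.322477, tolerance = 1e-5)
  # an inner argument of exactly 1 gives F = 0: solve beta/sigma freely
  co <- model_coefficients(alpha = 0, beta = 0)
  expect_identical(f_term(2, 0.5, 0.5, 0.5, co), 0)  # inner = 2*0.5 = 1
})

test_that("the F term is monotone in its descriptors", {
  sig <- seq(0.1, 1.5, length.out = 40)
  Fs <- f_term(3, 0.3, sig / 2, sig / 2)
  expect_true(all(diff(Fs) < 0))     # decreasing in sigma
  chis <- seq(2, 6, length.out = 40)
  Fc <- f_term(chis, 0.3, 0.25, 0.25)
  expect_true(all(diff(Fc) > 0))     # increasing in chi_M
})

test_that("F-term domain violations are errors, not protected values", {
  expect_error(f_term(2, 0.5, 0, 0), "s2_plus \\+ s5_plus")
  expect_error(f_term(2, 0.5, -0.3, 0.1), "s2_plus \\+ s5_plus")
  # force a negative log argument with a negative chi and zero beta
  co <- model_coefficients(beta = 0)
  expect_error(f_term(-2, 0.5, 0.5, 0.5, co), "non-positive")
})

test_that("the ideal-scale prediction matches hand evaluation", {
  pred <- predict_log_krel_ideal(q2 = 0.05, q5 = 0.05, chi_M = 2,
                                 S_global = 0.5, s2_plus = 1.5,
                                 s5_plus = 1.575)
  expect_equal(pred, -46.397, tolerance = 1e-3)
  # with F = 0 and zero charges only the intercept remains
  co <- model_coefficients(alpha = 0, beta = 0)
  expect_identical(predict_log_krel_ideal(0, 0, 2, 0.5, 0.5, 0.5, co), 53.25)
  # linear in (q2 + q5): doubling 0.1 -> 0.2 adds exactly 8.61 * 0.1
  p1 <- predict_log_krel_ideal(0.05, 0.05, 2, 0.5, 1.5, 1.575)
  p2 <- predict_log_krel_ideal(0.10, 0.10, 2, 0.5, 1.5, 1.575)
  expect_equal(p2 - p1, 0.861)
})

test_that("the methanol calibration is the published affine map", {
  expect_identical(calibrate_to_methanol(0), 8.646)
  expect_equal(calibrate_to_methanol(-3.39), 6.866, tolerance = 1e-3)
  # order preserving
  expect_lt(calibrate_to_methanol(-5), calibrate_to_methanol(-1))
})

test_that("prediction then calibration is affine in F with slope -39.90", {
  base <- predict_reactivity(
    tibble::tibble(q2 = 0, q5 = 0, chi_M = c(2, 3), S_global = 0.3,
                   s2_plus = 0.25, s5_plus = 0.25),
    classify = FALSE)
  slope <- diff(base$log_krel_methanol) / diff(base$F_term)
  expect_equal(slope, -76.00 * 0.525, tolerance = 1e-9)
  expect_equal(-76.00 * 0.525, -39.90)
})

test_that("fitting the calibration recovers planted affine constants", {
  set.seed(1)
  ideal <- runif(20, -8, 0)
  observed <- 0.525 * ideal + 8.646
  fit <- fit_linear_calibration(ideal, observed)
  expect_lt(abs(fit$coefficients$slope - 0.525), 1e-10)
  expect_lt(abs(fit$coefficients$intercept - 8.646), 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # destroying the pairing lowers the correlation
  perm <- fit_linear_calibration(ideal, sample(observed))
  expect_lt(perm$r2, fit$r2)

  expect_error(fit_linear_calibration(1:2, 1:2), "at least 3")
  expect_error(fit_linear_calibration(rep(1, 5), 1:5), "degenerate")

  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(8.646, 0.525), tolerance = 1e-9)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-12)
})

test_that("the baseline electronegativity model recovers planted lines", {
  set.seed(2)
  d <- tibble::tibble(
    species_id = sprintf("s%02d", 1:20),
    chi_M = runif(20, 2, 6)
  )
  d$log_krel <- -4.1 + 12.3 * log10(d$chi_M)
  fit <- fit_baseline_chiM(d)
  expect_equal(fit$slope, 12.3, tolerance = 1e-9)
  expect_equal(fit$intercept, -4.1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # a planted outlier depresses r2; excluding it restores the fit
  d2 <- d
  d2$log_krel[7] <- d2$log_krel[7] + 25
  with_out <- fit_baseline_chiM(d2)
  without <- fit_baseline_chiM(d2, exclude = "s07")
  expect_lt(with_out$r2, without$r2)
  expect_equal(without$r2, 1, tolerance = 1e-12)

  expect_error(fit_baseline_chiM(d[1:2, ]), "at least 3")
  d3 <- d; d3$chi_M[1] <- -1
  expect_error(fit_baseline_chiM(d3), "chi_M")
})

test_that("classification applies inclusive thresholds on both scales", {
  expect_identical(classify_reactivity(-3.39)$classification, "efficient")
  expect_identical(classify_reactivity(-3.0)$classification, "efficient")
  expect_identical(classify_reactivity(-2.9)$classification, "safer")
  m <- classify_reactivity(log_krel_methanol = c(-4.0, -3.9))
  expect_identical(m$classification, c("efficient", "safer"))
  expect_identical(m$threshold_basis, c("methanol", "methanol"))
  expect_error(classify_reactivity(NA_real_, NA_real_), "at least one")
})

test_that("when the two scales disagree, the ideal verdict wins with a warning", {
  # ideal says efficient, methanol scale says safer
  expect_warning(
    out <- classify_reactivity(log_krel_ideal = -3.5, log_krel_methanol = 0),
    "disagree")
  expect_identical(out$classification, "efficient")
  expect_identical(out$threshold_basis, "ideal")
})

test_that("residual SD behaves like a sample standard deviation", {
  expect_identical(residual_sd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(residual_sd(c(1, -1), c(0, 0)), sqrt(2))
  r <- c(0.3, -0.9, 1.4, 0.2)
  expect_equal(residual_sd(r + 5, rep(0, 4)), residual_sd(r, rep(0, 4)))
  expect_error(residual_sd(1:3, 1:4), "equal length")
})

test_that("the pipeline verb validates its input and appends columns", {
  recs <- generate_species(fixture_spec(seed = 21, n_species = 6))
  out <- predict_reactivity(thiophene_features(recs))
  expect_true(all(c("F_term", "log_krel_ideal", "log_krel_methanol",
                    "classification", "threshold_basis") %in% names(out)))
  expect_identical(nrow(out), 6L)
  expect_true(all(out$classification %in% c("efficient", "safer")))
  expect_error(predict_reactivity(tibble::tibble(q2 = 1)), "missing column")

  skinny <- predict_reactivity(thiophene_features(recs), cal = NULL,
                               classify = FALSE)
  expect_false("log_krel_methanol" %in% names(skinny))
})
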