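test_that("standard curve recovers exact and noisy linear calibrations", {
  ph <- seq(7.6, 9.0, by = 0.2)
  exact <- lapply(ph, function(p) rep(0.10 * p + 0.20, 5))
  cv <- fit_standard_curve(ph, exact)
  expect_equal(cv$slope, 0.10)
  expect_equal(cv$intercept, 0.20)
  expect_equal(cv$r_squared, 1)
  expect_equal(cv$n_standards, 8)

  set.seed(21)
  noisy_means <- 0.5 * ph - 3.3 + rnorm(length(ph), 0, 0.01)
  cvn <- fit_standard_curve(ph, as.list(noisy_means))
  oracle <- ols_oracle(ph, noisy_means)
  expect_equal(cvn$slope, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(cvn$intercept, unname(oracle["intercept"]), tolerance = 1e-12)

  # replicate wells of one pH averaged before the fit
  cvr <- fit_standard_curve(c(8, 8, 9), list(0.9, 1.1, 1.5))
  expect_equal(cvr$slope, 0.5)
  expect_error(fit_standard_curve(c(8, 8), list(1, 1)), "distinct")
})

test_that("absorbance inverts through the curve and flags out-of-range pH", {
  cv <- fit_standard_curve(c(7.6, 9.0), list(7.6, 9.0))  # identity curve
  expect_equal(as.numeric(absorbance_to_ph(8.0, cv)), 8.0)
  # round trip through a nontrivial curve
  cv2 <- fit_standard_curve(c(7.6, 9.0), list(0.5, 1.2))
  ph_in <- c(7.8, 8.4, 8.9)
  a <- cv2$intercept + cv2$slope * ph_in
  expect_equal(as.numeric(absorbance_to_ph(a, cv2)), ph_in)
  flagged <- absorbance_to_ph(cv2$intercept + cv2$slope * c(7.0, 8.0), cv2)
  expect_equal(attr(flagged, "outside_indicator_range"), c(TRUE, FALSE))
})

test_that("pH to proton conversion is the exact antilog", {
  expect_equal(ph_to_hplus(8.0), 1e-8)
  expect_equal(ph_to_hplus(0), 1)
  ph <- seq(9, 7, by = -0.1)  # decreasing pH => increasing [H+]
  expect_true(all(diff(ph_to_hplus(ph)) > 0))
  expect_equal(-log10(ph_to_hplus(ph)), ph)
  expect_error(ph_to_hplus(NaN), "non-finite")
})

test_that("nucleation and rate reproduce closed forms on a linear ramp", {
  t_s <- seq(0, 72000, by = 300)
  h0 <- 1e-8; dh <- 2e-8
  h <- h0 + dh * t_s / 72000
  # a pure ramp has no pre-nucleation plateau, so the baseline is the first
  # reading rather than a 10-point median
  cfg <- drift_config(baseline_points = 1)
  expect_equal(as.numeric(nucleation_time(t_s, h, cfg)), 2.0,
               tolerance = 1e-6)
  expect_equal(as.numeric(calcification_rate(t_s, h, cfg)), dh / 20,
               tolerance = 1e-6)
})

test_that("logistic curves match dense-grid and closed-form OLS oracles", {
  t_s <- assay_schedule()
  h0 <- ph_to_hplus(8.3); dh <- 2e-8; nuc <- 10 - log(9)  # t50 10 h, s 1 h
  rate <- dh / 4
  h <- logistic_h(t_s / 3600, h0, dh, nuc, rate)

  # crossing oracle on a 1-second grid
  t_dense <- seq(0, 72000, by = 1) / 3600
  h_dense <- logistic_h(t_dense, h0, dh, nuc, rate)
  base_o <- median(h_dense[1:10])
  dh_o <- max(h_dense) - base_o
  cross_o <- t_dense[which(h_dense >= base_o + 0.1 * dh_o)[1]]
  got <- as.numeric(nucleation_time(t_s, h))
  expect_lt(abs(got - cross_o), 300 / 3600)  # within one sampling interval
  expect_lt(abs(got - (10 - log(9))), 0.02)  # ~ t50 - s ln 9

  # rate equals lm() on the same selected points (independent regression)
  sm <- as.numeric(stats::runmed(h, 5, endrule = "median"))
  base <- median(h[1:10]); delta <- max(sm) - base
  sel <- sm >= base + 0.2 * delta & sm <= base + 0.6 * delta
  oracle_slope <- unname(coef(lm(h[sel] ~ I(t_s[sel] / 3600)))[2])
  expect_equal(as.numeric(calcification_rate(t_s, h)), oracle_slope,
               tolerance = 1e-9)
})

test_that("wells without precipitation are undefined and flagged", {
  t_s <- seq(0, 72000, by = 300)
  flat <- rep(1e-8, length(t_s))
  nt <- nucleation_time(t_s, flat)
  expect_true(is.na(nt))
  expect_true("no_precipitation" %in% attr(nt, "flags"))
  expect_true(is.na(as.numeric(calcification_rate(t_s, flat))))
  # noisy flat series stays below the 3-MAD floor
  set.seed(4)
  noisy_flat <- 1e-8 + rnorm(length(t_s), 0, 1e-11)
  expect_true(is.na(as.numeric(nucleation_time(t_s, noisy_flat))))
  expect_error(nucleation_time(c(0, 300), c(1e-8, 2e-8)), "smoothing window")
})

test_that("control normalization is the ratio to the control mean", {
  rec <- data.frame(role = c("control", "control", "sample"),
                    nucleation_h = c(8, 12, 5), rate = c(2, 2, 3))
  out <- normalize_to_controls(rec)
  expect_equal(out$norm_nucleation, c(0.8, 1.2, 0.5))
  expect_equal(out$norm_rate, c(1, 1, 1.5))
  # control group averages to 1 by construction
  expect_equal(mean(out$norm_nucleation[out$role == "control"]), 1)
  expect_error(normalize_to_controls(data.frame(role = "sample",
                                                nucleation_h = 1, rate = 1)),
               "no control")
})

test_that("normalized rates are invariant to a plate-wide delta-H scaling", {
  plan <- drift_plan(doses = c(0, 1), replicates = 2,
                     nucleation_h = c(4, 3), rate = c(1e-8, 1.5e-8))
  f1 <- drift_fit(simulate_drift_plate(plan))
  plan2 <- plan
  plan2$delta_h <- plan$delta_h * 2
  plan2$rate <- plan$rate * 2  # same shape, doubled amplitude
  f2 <- drift_fit(simulate_drift_plate(plan2))
  expect_equal(f1$records$norm_rate, f2$records$norm_rate, tolerance = 1e-6)
  expect_equal(f1$records$norm_nucleation, f2$records$norm_nucleation,
               tolerance = 1e-6)
})

test_that("nucleation is invariant under affine absorbance transforms", {
  plan <- drift_plan(doses = 0, replicates = 1, nucleation_h = 5)
  d1 <- simulate_drift_plate(plan, curve_slope = 0.5, curve_intercept = -3.3)
  d2 <- simulate_drift_plate(plan, curve_slope = 1.1, curve_intercept = 2.0)
  n1 <- drift_fit(d1)$records$nucleation_h
  n2 <- drift_fit(d2)$records$nucleation_h
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("for monotone series nucleation precedes the rate window", {
  t_s <- assay_schedule()
  h <- logistic_h(t_s / 3600, 1e-8, 2e-8, 6, 1e-8)
  cfg <- drift_config()
  nt <- as.numeric(nucleation_time(t_s, h, cfg))
  sm <- as.numeric(stats::runmed(h, 5, endrule = "median"))
  base <- median(h[1:10]); delta <- max(sm) - base
  sel <- sm >= base + 0.2 * delta & sm <= base + 0.6 * delta
  expect_true(all(nt <= t_s[sel] / 3600))
})

test_that("drift_fit recovers planted truth on a noiseless plate", {
  plan <- drift_plan(doses = c(0, 0.5), replicates = 3,
                     nucleation_h = c(4, 2), rate = c(1e-8, 2e-8))
  ds <- simulate_drift_plate(plan, noise_sd = 0)
  fit <- drift_fit(ds)
  expect_s3_class(fit, "drift_fit")
  rec <- fit$records
  truth <- attr(ds, "truth")
  truth <- truth[truth$role != "standard", ]
  expect_equal(rec$nucleation_h, truth$nucleation_h, tolerance = 300 / 3600)
  # standard curve recovered exactly from noiseless standards
  expect_equal(unname(coef(fit)), c(-3.3, 0.5), tolerance = 1e-9)
  # normalized control mean is 1; dose 0.5 wells halve the nucleation time
  expect_equal(mean(rec$norm_nucleation[rec$role == "control"]), 1)
  expect_equal(rec$norm_nucleation[rec$dose == 0.5], rep(0.5, 3),
               tolerance = 1e-3)
  s <- summary(fit)
  expect_s3_class(s, "summary.drift_fit")
  expect_equal(nrow(s), 2)
  expect_output(print(fit), "drift calcification")
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})
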