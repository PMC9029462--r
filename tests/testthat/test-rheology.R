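test_that("synthetic flow curves follow the measurement protocol", {
  fc <- synth_flow_curve("power_law", list(K = 10, n = 0.5))
  expect_equal(nrow(fc), 30)
  expect_equal(fc$shear_rate_1_per_s[1], 0.01)
  expect_equal(fc$shear_rate_1_per_s[30], 100)
  # logarithmic ascent: constant ratio between consecutive rates
  ratios <- diff(log10(fc$shear_rate_1_per_s))
  expect_equal(ratios, rep(ratios[1], 29), tolerance = 1e-12)
  # parameter validation
  expect_error(synth_flow_curve("power_law", list(K = -1, n = 0.5)), "K")
  expect_error(synth_flow_curve("cross",
                                list(eta0 = 1, eta_inf = 2, lambda = 1,
                                     m = 1)), "eta_inf < eta0")
})

test_that("power-law fits recover exact and noisy parameters", {
  # exact recovery
  fc <- synth_flow_curve("power_law", list(K = 10, n = 0.5))
  fit <- fit_power_law(fc)
  expect_equal(fit$K, 10, tolerance = 1e-9)
  expect_equal(fit$n, 0.5, tolerance = 1e-9)
  expect_true(fit$shear_thinning)
  # Newtonian limit: constant viscosity, not shear thinning
  nc <- synth_flow_curve("power_law", list(K = 2, n = 1))
  expect_equal(unique(round(nc$viscosity_Pa_s, 12)), 2)
  fitn <- fit_power_law(nc)
  expect_equal(fitn$n, 1, tolerance = 1e-9)
  expect_false(fitn$shear_thinning)
  # finite-difference slope oracle: every consecutive pair has slope n - 1
  expect_equal(oracle_loglog_slopes(fc), rep(-0.5, 29), tolerance = 1e-9)
  # noisy recovery at the emulated noise level
  noisy <- synth_flow_curve("power_law", list(K = 10, n = 0.5),
                            noise_sd = 0.05, seed = 21)
  fitz <- fit_power_law(noisy)
  expect_lt(abs(fitz$n - 0.5) / 0.5, 0.05)
  expect_error(fit_power_law(fc[1:2, ]), "3 points")
})

test_that("Cross fits recover parameters and flag degeneracy", {
  cc <- synth_flow_curve("cross",
                         list(eta0 = 5, eta_inf = 0.1, lambda = 2, m = 1))
  fit <- fit_cross(cc)
  expect_equal(fit$eta0, 5, tolerance = 1e-6)
  expect_equal(fit$eta_inf, 0.1, tolerance = 1e-6)
  expect_equal(fit$lambda, 2, tolerance = 1e-6)
  expect_equal(fit$m, 1, tolerance = 1e-6)
  expect_true(fit$shear_thinning)
  # Newtonian data degenerate to eta0 ~ eta_inf, flagged not failed
  nc <- synth_flow_curve("power_law", list(K = 2, n = 1))
  fitn <- fit_cross(nc)
  expect_true(fitn$degenerate)
  expect_equal(fitn$eta0, fitn$eta_inf)
  # noisy recovery across seeds; 3% noise keeps eta_inf identifiable
  # from the few near-plateau points the protocol provides
  errs0 <- errsi <- numeric(10)
  for (s in 1:10) {
    noisy <- synth_flow_curve("cross",
                              list(eta0 = 5, eta_inf = 0.1, lambda = 2,
                                   m = 1), noise_sd = 0.03, seed = s)
    f <- fit_cross(noisy)
    errs0[s] <- abs(f$eta0 - 5) / 5
    errsi[s] <- abs(f$eta_inf - 0.1) / 0.1
  }
  expect_true(all(errs0 < 0.10))
  expect_true(all(errsi < 0.10))
})

test_that("viscosity interpolation is exact where it should be", {
  fc <- synth_flow_curve("power_law", list(K = 10, n = 0.5))
  # grid point: that point's value
  expect_equal(viscosity_at(fc, fc$shear_rate_1_per_s[7]),
               fc$viscosity_Pa_s[7], tolerance = 1e-12)
  # between points on a power law: the analytic value
  expect_equal(viscosity_at(fc, 50), 10 * 50^(0.5 - 1), tolerance = 1e-9)
  expect_equal(viscosity_at(fc, 0.37), 10 * 0.37^(-0.5), tolerance = 1e-9)
  # no extrapolation
  expect_error(viscosity_at(fc, 500), "outside the measured range")
  # two solutions built to share eta(50): interpolations agree within 2%
  cross_p <- list(eta0 = 5, eta_inf = 0.08, lambda = 1.5, m = 0.9)
  eta50 <- cross_p$eta_inf +
    (cross_p$eta0 - cross_p$eta_inf) / (1 + (cross_p$lambda * 50)^cross_p$m)
  K <- eta50 / 50^(0.55 - 1)
  p1_like <- synth_flow_curve("cross", cross_p)
  c1_like <- synth_flow_curve("power_law", list(K = K, n = 0.55))
  v1 <- viscosity_at(p1_like, 50); v2 <- viscosity_at(c1_like, 50)
  expect_lt(abs(v1 - v2) / v2, 0.02)
})

test_that("fitted models beat a constant-viscosity fit on thinning data", {
  noisy <- synth_flow_curve("power_law", list(K = 8, n = 0.4),
                            noise_sd = 0.05, seed = 3)
  le <- log(noisy$viscosity_Pa_s)
  fit <- fit_power_law(noisy)
  pred <- log(fit$K) + (fit$n - 1) * log(noisy$shear_rate_1_per_s)
  expect_lt(sum((le - pred)^2), sum((le - mean(le))^2))
})

test_that("flow curves round-trip through CSV", {
  fc <- synth_flow_curve("power_law", list(K = 3, n = 0.7),
                         noise_sd = 0.02, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_flow_curve(fc, path)
  expect_equal(readLines(path, n = 1),
               "\"shear_rate_1_per_s\",\"viscosity_Pa_s\"")
  back <- read_flow_curve(path)
  expect_equal(back$viscosity_Pa_s, fc$viscosity_Pa_s, tolerance = 1e-9)
})
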