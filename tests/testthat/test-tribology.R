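constant_mu_scenario <- function(mu = 0.3, duration = 20) {
  build_scenario("P1", "btm", overrides = list(
    duration_s = duration, true_endpoint_s = duration / 2,
    events = list(),
    cof_signature = list(shape = "fluctuate_plateau", mu_initial = mu,
                         mu_plateau = mu, fluctuation_amp = 0,
                         noise_sd = 0, transition_s = duration / 2)))
}

test_that("trace synthesis honours the sampling and kinematic settings", {
  sc <- build_scenario("C2", "btm")
  tr60 <- synth_friction_trace(sc, seed = 1, duration_s = 60)
  expect_equal(nrow(tr60), 6000)              # 100 Hz for 60 s
  expect_equal(max(tr60$pos_mm), 7.5, tolerance = 0.01)
  expect_equal(min(tr60$pos_mm), 0)
  expect_equal(attr(tr60, "frequency_hz"), 1)
  expect_equal(mean(tr60$fn_N), 1, tolerance = 0.01)
  expect_error(synth_friction_trace(build_scenario("P1", "ocm")),
               "BTM")
})

test_that("noiseless constant-mu traces give the scripted ratio exactly", {
  sc <- constant_mu_scenario(0.3)
  tr <- synth_friction_trace(sc, seed = 1, fn_noise_sd_N = 0)
  res <- sqrt(tr$ff1_N^2 + tr$ff2_N^2)
  expect_equal(res / tr$fn_N, rep(0.3, nrow(tr)), tolerance = 1e-12)
  series <- compute_cof(tr)
  expect_true(all(series$valid))
  expect_equal(series$mu, rep(0.3, nrow(series)), tolerance = 1e-12)
})

test_that("the sample-level change point sits at the scripted transition", {
  # step signature (no decline ramp), noiseless: exhaustive single
  # change-point least-squares scan over samples must break at 8 s
  sc <- build_scenario("C2", "btm", overrides = list(
    cof_signature = list(decline_s = 0, noise_sd = 0)))
  tr <- synth_friction_trace(sc, seed = 2, fn_noise_sd_N = 0,
                             duration_s = 16)
  mu <- sqrt(tr$ff1_N^2 + tr$ff2_N^2) / tr$fn_N
  o <- oracle_changepoints(mu, max_cp = 1, min_segment = 2)
  expect_equal(o$k, 1L)
  expect_equal(tr$t_s[o$cps], 8.0)
})

test_that("per-stroke mu recovers the scripted signature", {
  # noiseless: stroke means reproduce the script to within 1%
  sc0 <- build_scenario("C2", "btm",
                        overrides = list(cof_signature =
                                           list(noise_sd = 0)))
  s0 <- compute_cof(synth_friction_trace(sc0, seed = 3,
                                         fn_noise_sd_N = 0))
  sig <- sc0$cof_signature
  s0 <- s0[s0$valid, ]
  pre0 <- s0$mu[s0$t_mid_s < sig$transition_s - sig$decline_s - 1]
  post0 <- s0$mu[s0$t_mid_s > sig$transition_s + 1]
  expect_true(all(abs(pre0 - sig$mu_initial) / sig$mu_initial < 0.01))
  expect_true(all(abs(post0 - sig$mu_plateau) / sig$mu_plateau < 0.01))
  # at the packaged noise level the stroke means stay within 5%
  sc <- build_scenario("C2", "btm")
  series <- compute_cof(synth_friction_trace(sc, seed = 3))
  series <- series[series$valid, ]
  pre <- series$mu[series$t_mid_s < sig$transition_s - sig$decline_s - 1]
  post <- series$mu[series$t_mid_s > sig$transition_s + 1]
  expect_true(all(abs(pre - sig$mu_initial) / sig$mu_initial < 0.05))
  expect_true(all(abs(post - sig$mu_plateau) / sig$mu_plateau < 0.08))
})

test_that("mu is invariant to force-channel scaling and fn floors work", {
  sc <- constant_mu_scenario(0.4)
  tr <- synth_friction_trace(sc, seed = 4)
  s1 <- compute_cof(tr)
  tr2 <- tr
  tr2$ff1_N <- tr$ff1_N * 3.7; tr2$ff2_N <- tr$ff2_N * 3.7
  tr2$fn_N <- tr$fn_N * 3.7
  s2 <- compute_cof(tr2)
  expect_equal(s1$mu, s2$mu, tolerance = 1e-12)
  # a stroke with fn below the floor is flagged invalid, not dropped
  tr3 <- tr
  tr3$fn_N[tr3$t_s >= 5 & tr3$t_s < 6] <- 0
  s3 <- compute_cof(tr3)
  row <- s3[s3$stroke_index == 6, ]
  expect_false(row$valid)
  expect_equal(nrow(s3), nrow(s1))
  # fn = 0 throughout is an explicit failure
  tr4 <- tr; tr4$fn_N <- 0
  expect_error(compute_cof(tr4), "no valid strokes")
})

test_that("mean_cof averages valid strokes and honours until_s", {
  sc <- constant_mu_scenario(0.3)
  series <- compute_cof(synth_friction_trace(sc, seed = 5,
                                             fn_noise_sd_N = 0))
  expect_equal(mean_cof(series), 0.3, tolerance = 1e-12)
  two <- series[1:2, ]
  two$mu <- c(0.2, 0.4)
  attr(two, "stroke_period_s") <- 1
  class(two) <- c("cof_series", "data.frame")
  expect_equal(mean_cof(two), 0.3)
  # truncation before the decline recovers the initial level
  c2 <- build_scenario("C2", "btm")
  s2 <- compute_cof(synth_friction_trace(c2, seed = 6))
  expect_equal(mean_cof(s2, until_s = 4.9),
               c2$cof_signature$mu_initial, tolerance = 0.01)
})

test_that("friction endpoint detection handles plateaus and null cases", {
  # constant series: no change point, censored
  sc <- constant_mu_scenario(0.35)
  series <- compute_cof(synth_friction_trace(sc, seed = 7))
  ep <- detect_friction_endpoint(series)
  expect_true(ep$censored)
  # decline-plateau: terminal plateau onset near the scripted transition
  c2 <- build_scenario("C2", "btm")
  s2 <- compute_cof(synth_friction_trace(c2, seed = 8))
  ep2 <- detect_friction_endpoint(s2)
  expect_false(ep2$censored)
  expect_lt(abs(ep2$time_s - 8.0), 2.0)
  # fluctuate-plateau: only the terminal plateau onset is reported
  p2 <- build_scenario("P2", "btm")
  sp <- compute_cof(synth_friction_trace(p2, seed = 9))
  epp <- detect_friction_endpoint(sp)
  expect_false(epp$censored)
  expect_lt(abs(epp$time_s - 21.0), 2.0)
  # too few strokes is a refusal, not a guess
  short <- series[1:5, ]
  class(short) <- c("cof_series", "data.frame")
  expect_error(detect_friction_endpoint(short), "at least 10")
})

test_that("selected change points equal exhaustive-search change points", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(20:60, 1)
    k_true <- sample(0:2, 1)
    cps <- sort(sample(5:(n - 5), k_true))
    means <- cumsum(c(0.4, stats::runif(k_true, -0.2, 0.2)))
    y <- numeric(n)
    bounds <- c(1, cps, n + 1)
    for (s in seq_len(length(bounds) - 1))
      y[bounds[s]:(bounds[s + 1] - 1)] <- means[s]
    y <- y + stats::rnorm(n, 0, 0.02)
    mine <- odftoolbox:::fit_piecewise_constant(y, 2, 2)
    orac <- oracle_changepoints(y, 2, 2)
    expect_equal(mine$k, orac$k)
    expect_equal(mine$cps, orac$cps)
    expect_equal(mine$rss, orac$rss, tolerance = 1e-9)
  }
})

test_that("BIC never overfits noiseless signatures", {
  # constant: k = 0
  expect_equal(odftoolbox:::fit_piecewise_constant(rep(0.3, 40))$k, 0L)
  # single step: k = 1
  y <- c(rep(0.3, 20), rep(0.18, 20))
  expect_equal(odftoolbox:::fit_piecewise_constant(y)$k, 1L)
  # two steps: k = 2
  y2 <- c(rep(0.3, 15), rep(0.24, 10), rep(0.18, 15))
  expect_equal(odftoolbox:::fit_piecewise_constant(y2)$k, 2L)
})

test_that("group comparison matches the closed-form ANOVA oracle", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  st <- compare_groups(g)
  o <- oracle_anova(g)
  expect_equal(st$anova_F, o$F, tolerance = 1e-12)
  expect_equal(st$anova_p, o$p, tolerance = 1e-12)
  expect_equal(nrow(st$tukey), 3)
  # identical groups: F = 0, p = 1
  st0 <- compare_groups(list(a = c(2, 3, 4), b = c(2, 3, 4)))
  expect_equal(st0$anova_F, 0)
  expect_equal(st0$anova_p, 1)
  # malformed input
  expect_error(compare_groups(list(a = 1:3)), "at least 2 groups")
  expect_error(compare_groups(list(a = 1:3, b = 2)), "replicates")
})

test_that("friction traces round-trip through the CSV interchange format", {
  sc <- build_scenario("C1", "btm")
  tr <- synth_friction_trace(sc, seed = 10, duration_s = 3)
  path <- tempfile(fileext = ".csv")
  write_friction_trace(tr, path)
  expect_equal(readLines(path, n = 1),
               "\"time_s\",\"ff1_N\",\"ff2_N\",\"fn_N\",\"pos_mm\"")
  back <- read_friction_trace(path)
  expect_equal(back$ff1_N, tr$ff1_N, tolerance = 1e-9)
  s1 <- compute_cof(tr); s2 <- compute_cof(back)
  expect_equal(s1$mu, s2$mu, tolerance = 1e-9)
})
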