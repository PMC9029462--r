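cof_mu_at <- function(sig, t) {
  mu <- rep(sig$mu_plateau, length(t))
  pre <- t < sig$transition_s
  if (identical(sig$shape, "decline_plateau")) {
    d <- sig$decline_s %||% 0
    ramp <- pre & t >= sig$transition_s - d
    mu[pre] <- sig$mu_initial
    if (d > 0 && any(ramp)) {
      frac <- (t[ramp] - (sig$transition_s - d)) / d
      mu[ramp] <- sig$mu_initial + frac * (sig$mu_plateau - sig$mu_initial)
    }
  } else {  # fluctuate_plateau
    period <- sig$fluctuation_period_s %||% 5
    amp <- sig$fluctuation_amp %||% 0
    mu[pre] <- sig$mu_initial + amp * sin(2 * pi * t[pre] / period)
  }
  mu
}

#' Synthesise a BioTribometer friction trace
#'
#' Generates the four 100 Hz channels of a reciprocating flat-on-flat
#' friction test: triangular stage position (7.5 mm stroke at 1 Hz),
#' normal force (nominal 1 N plus noise) and two friction-force channels
#' laid at a fixed in-plane angle whose Euclidean resultant has magnitude
#' mu(t) times the normal force, signed by sliding direction. mu(t)
#' follows the scenario's friction signature: CMC-like films decline
#' rapidly to a terminal plateau as the film disintegrates; PVA-like
#' films fluctuate before plateauing. Sample-level Gaussian noise with
#' the signature's stated sd is added to mu.
#'
#' @param scenario A BTM `film_scenario`.
#' @param seed Integer seed.
#' @param duration_s Trace duration (default: scenario duration).
#' @param fn_noise_sd_N Normal-force noise sd (default: packaged value;
#'   set 0 for a noiseless trace).
#' @return A `friction_trace` data frame with columns `t_s`, `ff1_N`,
#'   `ff2_N`, `fn_N`, `pos_mm` and attributes `sample_hz`,
#'   `frequency_hz`, `load_N`, `ssf_ul_per_4_strokes`, `film_id`, `seed`.
#' @export
synth_friction_trace <- function(scenario, seed = scenario$seed,
                                 duration_s = NULL,
                                 fn_noise_sd_N = NULL) {
  stopifnot(inherits(scenario, "film_scenario"))
  if (scenario$method != "btm")
    stop("friction traces only exist for BTM scenarios")
  sig <- scenario$cof_signature
  btm <- odf_params()$btm
  dur <- duration_s %||% scenario$duration_s
  n <- as.integer(round(dur * btm$sample_hz))
  t <- (seq_len(n) - 1) / btm$sample_hz
  phase <- (t * btm$frequency_hz) %% 1
  pos <- btm$stroke_mm * (1 - abs(2 * phase - 1))
  dirn <- ifelse(phase < 0.5, 1, -1)

  set.seed(derive_seed(seed, 0L))
  fn <- btm$load_N + rnorm(n, 0, fn_noise_sd_N %||% btm$fn_noise_sd_N)
  mu <- cof_mu_at(sig, t) + rnorm(n, 0, sig$noise_sd %||% 0)
  theta <- (btm$channel_angle_deg %||% 0) * pi / 180
  ff <- dirn * mu * fn
  trace <- data.frame(t_s = t, ff1_N = ff * cos(theta),
                      ff2_N = ff * sin(theta), fn_N = fn, pos_mm = pos)
  structure(trace,
            class = c("friction_trace", "data.frame"),
            sample_hz = btm$sample_hz, frequency_hz = btm$frequency_hz,
            load_N = btm$load_N,
            ssf_ul_per_4_strokes = btm$ssf_ul_per_4_strokes,
            film_id = scenario$film$film_id, seed = seed)
}

#' Simulated-salivary-fluid dosing rate
#'
#' Converts the manual dosing schedule (microlitres delivered every
#' `per_strokes` reciprocation strokes at `frequency_hz` strokes per
#' second) into a flow rate in mL/min. With the packaged schedule of
#' 100 uL per four strokes at 1 Hz this is exactly 1.5 mL/min.
#'
#' @param ul Volume per bolus in microlitres.
#' @param per_strokes Strokes between boluses.
#' @param frequency_hz Stroke rate in strokes per second.
#' @return Flow rate in mL/min.
#' @export
ssf_flow_rate_ml_min <- function(ul = odf_params()$btm$ssf_ul_per_4_strokes,
                                 per_strokes = 4,
                                 frequency_hz = odf_params()$btm$frequency_hz) {
  stopifnot(ul > 0, per_strokes > 0, frequency_hz > 0)
  (ul / 1000) / (per_strokes / frequency_hz) * 60
}

#' Coefficient-of-friction computation settings
#'
#' @param frequency_hz Reciprocation frequency used to delimit strokes
#'   when no stage-position channel is available.
#' @param fn_floor_N Samples with normal force below this floor are
#'   excluded (the ratio is ill-conditioned there).
#' @param central_fraction Fraction of the positional stroke range kept;
#'   samples near the turnarounds are masked because sliding velocity
#'   passes through zero and instantaneous friction is ill-defined.
#' @return A `cof_config` list.
#' @export
cof_config <- function(frequency_hz = 1, fn_floor_N = 0.1,
                       central_fraction = 0.6) {
  stopifnot(frequency_hz > 0, fn_floor_N >= 0,
            central_fraction > 0, central_fraction <= 1)
  structure(list(frequency_hz = frequency_hz, fn_floor_N = fn_floor_N,
                 central_fraction = central_fraction),
            class = "cof_config")
}

#' Per-stroke coefficient of friction from a force trace
#'
#' Sample-level mu is the Euclidean resultant of the two friction-force
#' channels divided by the normal force; samples with normal force below
#' the configured floor are excluded. Strokes (full reciprocation cycles)
#' are delimited from the stage-position channel when present, otherwise
#' from the configured frequency, and each stroke's mu is the mean of
#' valid samples within the central portion of the positional range
#' (turnaround masking). Strokes whose samples are all excluded are kept
#' in the output flagged invalid rather than silently dropped.
#'
#' @param trace A `friction_trace` (or any data frame with `t_s`,
#'   `ff1_N`, `ff2_N`, `fn_N` and optionally `pos_mm`).
#' @param config A [cof_config()].
#' @return A `cof_series` data frame: `stroke_index`, `t_mid_s`, `mu`,
#'   `n_valid_samples`, `valid`; attribute `stroke_period_s`.
#' @export
compute_cof <- function(trace, config = cof_config()) {
  need <- c("t_s", "ff1_N", "ff2_N", "fn_N")
  if (!all(need %in% names(trace)))
    stop("trace must contain columns: ", paste(need, collapse = ", "))
  n <- nrow(trace)
  if (n == 0) stop("empty trace")
  mu <- sqrt(trace$ff1_N^2 + trace$ff2_N^2) / trace$fn_N
  valid <- is.finite(mu) & trace$fn_N >= config$fn_floor_N

  if ("pos_mm" %in% names(trace) && any(is.finite(trace$pos_mm))) {
    pos <- trace$pos_mm
    rng <- range(pos, finite = TRUE)
    span <- diff(rng)
    # stroke boundaries at position minima (cycle starts): within every
    # run of near-minimum samples, the minimum itself delimits the cycle;
    # epsilon keeps samples sitting exactly on a cutoff stable under IO
    # rounding
    eps <- 1e-6 * span
    low <- pos <= rng[1] + 0.02 * span + eps
    r <- rle(low)
    run_ends <- cumsum(r$lengths)
    run_starts <- run_ends - r$lengths + 1
    runs <- which(r$values & run_ends < n)  # a run touching the final
    # sample is a clipped descent with no complete stroke after it
    starts <- vapply(runs, function(k) {
      s <- run_starts[k]; e <- run_ends[k]
      s - 1 + which.min(pos[s:e])
    }, numeric(1))
    stroke0 <- findInterval(seq_len(n), starts)
    stroke <- stroke0 - min(stroke0) + 1L
    margin <- (1 - config$central_fraction) / 2
    central <- pos >= rng[1] + margin * span - eps &
      pos <= rng[2] - margin * span + eps
  } else {
    period <- 1 / config$frequency_hz
    stroke <- as.integer(floor(trace$t_s / period)) + 1L
    phase <- (trace$t_s %% period) / period
    # turnarounds of a symmetric reciprocation sit at phase 0, 1/2, 1
    margin <- (1 - config$central_fraction) / 4
    central <- abs(phase %% 0.5 - 0.25) <= (0.25 - margin)
  }

  use <- valid & central
  if (!any(use))
    stop("no valid strokes: all samples excluded ",
         "(normal force below floor or turnaround-masked)")
  idx <- sort(unique(stroke))
  rows <- lapply(idx, function(s) {
    in_s <- stroke == s
    k <- use & in_s
    data.frame(stroke_index = s,
               t_mid_s = mean(range(trace$t_s[in_s])),
               mu = if (any(k)) mean(mu[k]) else NA_real_,
               n_valid_samples = sum(k),
               valid = any(k))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("cof_series", "data.frame"),
            stroke_period_s = if ("pos_mm" %in% names(trace))
              stats::median(diff(out$t_mid_s)) else 1 / config$frequency_hz)
}

#' Mean coefficient of friction over the test
#'
#' Unweighted mean of valid per-stroke mu values, optionally truncated at
#' `until_s`.
#'
#' @param series A `cof_series`.
#' @param until_s Optional truncation time (default: whole test).
#' @return Mean mu (numeric scalar).
#' @export
mean_cof <- function(series, until_s = NULL) {
  stopifnot(inherits(series, "cof_series"))
  keep <- series$valid
  if (!is.null(until_s)) keep <- keep & series$t_mid_s <= until_s
  if (!any(keep)) stop("no valid strokes in the requested window")
  mean(series$mu[keep])
}

# exact piecewise-constant least-squares fits with 0..max_cp change
# points, via cumulative sums; change points are segment start indices
fit_piecewise_constant <- function(y, max_cp = 2, min_segment = 2) {
  n <- length(y)
  c1 <- cumsum(y); c2 <- cumsum(y^2)
  segcost <- function(a, b) {  # inclusive indices, vectorised over a or b
    s1 <- c1[b] - ifelse(a > 1, c1[a - 1], 0)
    s2 <- c2[b] - ifelse(a > 1, c2[a - 1], 0)
    s2 - s1^2 / (b - a + 1)
  }
  fits <- list()
  fits[[1]] <- list(k = 0L, cps = integer(0), rss = segcost(1, n))
  if (max_cp >= 1 && n >= 2 * min_segment) {
    sp <- (min_segment + 1):(n - min_segment + 1)
    rss1 <- segcost(1, sp - 1) + segcost(sp, n)
    i <- which.min(rss1)
    fits[[2]] <- list(k = 1L, cps = sp[i], rss = rss1[i])
  }
  if (max_cp >= 2 && n >= 3 * min_segment) {
    best <- Inf; bestcp <- NULL
    for (i in (min_segment + 1):(n - 2 * min_segment + 1)) {
      j <- (i + min_segment):(n - min_segment + 1)
      r <- segcost(1, i - 1) + segcost(i, j - 1) + segcost(j, n)
      m <- which.min(r)
      if (r[m] < best) { best <- r[m]; bestcp <- c(i, j[m]) }
    }
    if (!is.null(bestcp))
      fits[[3]] <- list(k = 2L, cps = bestcp, rss = best)
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  bic <- vapply(fits, function(f)
    n * log(max(f$rss, 1e-12) / n) + (2 * f$k + 1) * log(n), numeric(1))
  sel <- fits[[which.min(bic)]]
  sel$bic <- bic
  sel$means <- {
    bounds <- c(1, sel$cps, n + 1)
    vapply(seq_len(length(bounds) - 1), function(s)
      mean(y[bounds[s]:(bounds[s + 1] - 1)]), numeric(1))
  }
  sel
}

#' Detect disintegration from the friction signature
#'
#' Fits piecewise-constant models with 0, 1 and 2 change points to the
#' valid per-stroke mu series by exact least squares and selects among
#' them by BIC. Disintegration time is the onset of the terminal plateau
#' segment (the last change point), which handles both the
#' decline-then-plateau (CMC-like) and fluctuate-then-plateau (PVA-like)
#' signatures. If the zero-change-point model is selected the series has
#' no plateau onset and the result is right-censored.
#'
#' @param series A `cof_series` with at least 10 valid strokes.
#' @param cap_s Censoring cap in seconds.
#' @param max_changepoints Maximum change points considered (default 2).
#' @param min_segment Minimum strokes per fitted segment (default 2).
#' @return An [endpoint_result()] with source `"friction_changepoint"`
#'   and attribute `fit` (the selected piecewise fit).
#' @export
detect_friction_endpoint <- function(series, cap_s = 180,
                                     max_changepoints = 2,
                                     min_segment = 2) {
  stopifnot(inherits(series, "cof_series"))
  ok <- series[series$valid, , drop = FALSE]
  if (nrow(ok) < 10)
    stop("need at least 10 valid strokes for change-point detection")
  fit <- fit_piecewise_constant(ok$mu, max_changepoints, min_segment)
  period <- attr(series, "stroke_period_s") %||% 1
  if (fit$k == 0L) {
    res <- endpoint_result(NA_real_, TRUE, cap_s, "friction_changepoint")
  } else {
    onset <- ok$t_mid_s[fit$cps[fit$k]] - period / 2
    res <- if (onset > cap_s)  # plateau begins after the cap: censored
      endpoint_result(NA_real_, TRUE, cap_s, "friction_changepoint")
    else
      endpoint_result(onset, FALSE, cap_s, "friction_changepoint")
  }
  attr(res, "fit") <- fit
  res
}

#' One-way ANOVA with Tukey's multiple comparison test
#'
#' Replicate-level group comparison as used for Petri-dish disintegration
#' times and mean coefficients of friction: one-way analysis of variance
#' followed by Tukey's honestly-significant-difference test on all pairs.
#'
#' @param groups Named list of numeric vectors: at least 2 groups, each
#'   with at least 2 replicates.
#' @param alpha Significance level recorded in the result.
#' @return A `group_stats` list: `means`, `sds`, `n`, `anova_F`,
#'   `anova_p`, `tukey` (data frame with pair, diff, adjusted p),
#'   `alpha`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2 || is.null(names(groups)))
    stop("groups must be a named list with at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop("every group needs at least 2 replicates; offending: ",
         paste(names(groups)[sizes < 2], collapse = ", "))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), sizes),
                                  levels = names(groups)))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(
    means = vapply(groups, mean, numeric(1)),
    sds = vapply(groups, sd, numeric(1)),
    n = sizes,
    anova_F = an[["F value"]][1],
    anova_p = an[["Pr(>F)"]][1],
    tukey = tukey, alpha = alpha), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats: %d groups, F = %.4g, p = %.4g>\n",
              length(x$means), x$anova_F, x$anova_p))
  invisible(x)
}

#' Write / read a friction trace as CSV
#'
#' The CSV uses the interchange header
#' `time_s, ff1_N, ff2_N, fn_N, pos_mm`.
#'
#' @param trace A `friction_trace`.
#' @param path Output path.
#' @return `write_friction_trace` returns `path` invisibly;
#'   `read_friction_trace` returns a `friction_trace`.
#' @export
write_friction_trace <- function(trace, path) {
  out <- data.frame(time_s = trace$t_s, ff1_N = trace$ff1_N,
                    ff2_N = trace$ff2_N, fn_N = trace$fn_N,
                    pos_mm = trace$pos_mm)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_friction_trace
#' @export
read_friction_trace <- function(path) {
  x <- read.csv(path)
  need <- c("time_s", "ff1_N", "ff2_N", "fn_N")
  if (!all(need %in% names(x)))
    stop("friction-trace CSV must contain columns: ",
         paste(need, collapse = ", "))
  out <- data.frame(t_s = x$time_s, ff1_N = x$ff1_N, ff2_N = x$ff2_N,
                    fn_N = x$fn_N,
                    pos_mm = if ("pos_mm" %in% names(x)) x$pos_mm
                             else NA_real_)
  structure(out, class = c("friction_trace", "data.frame"))
}
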