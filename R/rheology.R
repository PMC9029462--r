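#' Synthesise a rotational-rheometry flow curve
#'
#' Emulates the stock-solution protocol: exactly `n_points` shear rates
#' ascending logarithmically over `range` (default 30 points on
#' 0.01 to 100 1/s), with viscosity drawn from a power-law
#' (eta = K * gamma^(n - 1)) or Cross
#' (eta = eta_inf + (eta0 - eta_inf) / (1 + (lambda * gamma)^m)) model
#' plus multiplicative log-normal noise.
#'
#' @param model `"power_law"` or `"cross"`.
#' @param params Named list of model parameters: `K`, `n` (power law) or
#'   `eta0`, `eta_inf`, `lambda`, `m` (Cross).
#' @param noise_sd Log-normal noise sd on log-viscosity (0 = exact).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param n_points Number of shear rates.
#' @param range Shear-rate range in 1/s.
#' @return A `flow_curve` data frame: `shear_rate_1_per_s`,
#'   `viscosity_Pa_s`.
#' @export
synth_flow_curve <- function(model = c("power_law", "cross"), params,
                             noise_sd = 0, seed = NULL, n_points = 30,
                             range = c(0.01, 100)) {
  model <- match.arg(model)
  stopifnot(n_points >= 2, range[1] > 0, range[2] > range[1],
            noise_sd >= 0)
  gamma <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_points)
  if (model == "power_law") {
    if (is.null(params$K) || params$K <= 0) stop("K must be positive")
    if (is.null(params$n)) stop("flow index n is required")
    eta <- params$K * gamma^(params$n - 1)
  } else {
    p <- params
    if (any(vapply(c("eta0", "eta_inf", "lambda", "m"),
                   function(k) is.null(p[[k]]), logical(1))))
      stop("cross model requires eta0, eta_inf, lambda, m")
    if (p$eta_inf >= p$eta0)
      stop("cross model requires eta_inf < eta0")
    if (p$lambda <= 0 || p$m <= 0)
      stop("cross model requires lambda > 0 and m > 0")
    eta <- p$eta_inf + (p$eta0 - p$eta_inf) / (1 + (p$lambda * gamma)^p$m)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    set.seed(derive_seed(seed, 0L))
    eta <- eta * exp(rnorm(n_points, 0, noise_sd))
  }
  structure(data.frame(shear_rate_1_per_s = gamma, viscosity_Pa_s = eta),
            class = c("flow_curve", "data.frame"),
            model = model, params = params, noise_sd = noise_sd)
}

validate_flow_curve <- function(curve) {
  need <- c("shear_rate_1_per_s", "viscosity_Pa_s")
  if (!all(need %in% names(curve)))
    stop("flow curve must contain columns: ", paste(need, collapse = ", "))
  g <- curve$shear_rate_1_per_s; e <- curve$viscosity_Pa_s
  if (any(g <= 0) || any(e <= 0))
    stop("shear rates and viscosities must be positive")
  if (is.unsorted(g, strictly = TRUE))
    stop("shear rates must be strictly ascending")
  invisible(curve)
}

#' Fit a power-law (Ostwald-de Waele) model to a flow curve
#'
#' Least-squares line in log(eta) vs log(gamma): the slope is n - 1 and
#' the intercept log(K). The film-forming solutions are shear thinning
#' when n is below 1 beyond a tolerance of 0.02 (chosen to separate
#' behaviour from measurement noise at the emulated noise level).
#'
#' @param curve A `flow_curve` with >= 3 points.
#' @return A `rheo_fit` list: `model = "power_law"`, `K`, `n`,
#'   `r2_loglog`, `shear_thinning`.
#' @export
fit_power_law <- function(curve) {
  validate_flow_curve(curve)
  if (nrow(curve) < 3) stop("need at least 3 points")
  lg <- log(curve$shear_rate_1_per_s); le <- log(curve$viscosity_Pa_s)
  fit <- lm(le ~ lg)
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  tss <- sum((le - mean(le))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  n <- slope + 1
  structure(list(model = "power_law", K = exp(icpt), n = n,
                 r2_loglog = r2,
                 shear_thinning = n < 1 - 0.02),
            class = "rheo_fit")
}

#' Fit a Cross model to a flow curve
#'
#' Nonlinear least squares for
#' eta(gamma) = eta_inf + (eta0 - eta_inf) / (1 + (lambda * gamma)^m),
#' initialised from the data extremes (eta0 from the lowest-shear
#' viscosity, eta_inf from the highest, lambda from the mid-decay shear
#' rate, m = 1). Near-Newtonian data degenerate to eta0 ~ eta_inf and are
#' flagged rather than failed; genuine non-convergence raises an error
#' carrying the residual summary.
#'
#' @param curve A `flow_curve` with >= 5 points.
#' @param init Optional named list overriding the automatic start values.
#' @return A `rheo_fit` list: `model = "cross"`, `eta0`, `eta_inf`,
#'   `lambda`, `m`, `r2_loglog`, `shear_thinning`, `degenerate`,
#'   `convergence`.
#' @export
fit_cross <- function(curve, init = NULL) {
  validate_flow_curve(curve)
  if (nrow(curve) < 5) stop("need at least 5 points")
  g <- curve$shear_rate_1_per_s; e <- curve$viscosity_Pa_s
  e0 <- e[1]; einf <- e[length(e)]
  mid <- (log(e0) + log(einf)) / 2
  lam0 <- 1 / g[which.min(abs(log(e) - mid))]
  start <- modifyList(list(eta0 = e0, eta_inf = max(einf, 1e-8),
                           lambda = max(lam0, 1e-6), m = 1),
                      init %||% list())
  # near-Newtonian data: the decay terms are unidentifiable; flag instead
  if (sd(log(e)) < 0.01) {
    return(structure(list(model = "cross", eta0 = mean(e),
                          eta_inf = mean(e), lambda = NA_real_,
                          m = NA_real_, r2_loglog = 0,
                          shear_thinning = FALSE, degenerate = TRUE,
                          convergence = "degenerate (eta0 ~ eta_inf)"),
                     class = "rheo_fit"))
  }
  # least squares on log-viscosity: residuals are relative, so the
  # low-viscosity plateau constrains eta_inf as strongly as the
  # low-shear plateau constrains eta0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      log(e) ~ log(eta_inf + (eta0 - eta_inf) / (1 + (lambda * g)^m)),
      start = start,
      lower = c(eta0 = 1e-10, eta_inf = 1e-10, lambda = 1e-8, m = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) err)
  if (inherits(fit, "error")) {
    pred <- start$eta_inf +
      (start$eta0 - start$eta_inf) / (1 + (start$lambda * g)^start$m)
    stop("cross fit failed to converge: ", conditionMessage(fit),
         " (log-residual sum of squares at start values: ",
         format(sum((log(e) - log(pred))^2)), ")")
  }
  cf <- as.list(coef(fit))
  lr <- residuals(fit)
  r2 <- 1 - sum(lr^2) / sum((log(e) - mean(log(e)))^2)
  rel_drop <- (cf$eta0 - cf$eta_inf) / cf$eta0
  structure(list(model = "cross", eta0 = cf$eta0, eta_inf = cf$eta_inf,
                 lambda = cf$lambda, m = cf$m, r2_loglog = r2,
                 shear_thinning = rel_drop > 0.02,
                 degenerate = rel_drop <= 0.02,
                 convergence = fit$convInfo$stopMessage %||% "converged"),
            class = "rheo_fit")
}

#' @export
print.rheo_fit <- function(x, ...) {
  if (x$model == "power_law")
    cat(sprintf("<rheo_fit power-law: K = %.4g Pa.s^n, n = %.4g, R2 = %.4f%s>\n",
                x$K, x$n, x$r2_loglog,
                if (x$shear_thinning) ", shear thinning" else ""))
  else
    cat(sprintf("<rheo_fit Cross: eta0 = %.4g, eta_inf = %.4g, lambda = %.4g s, m = %.4g%s>\n",
                x$eta0, x$eta_inf, x$lambda, x$m,
                if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Interpolate viscosity at a shear rate
#'
#' Log-log linear interpolation between the bracketing measured points;
#' exact on power-law data for any in-range query. Extrapolation is
#' refused.
#'
#' @param curve A `flow_curve`.
#' @param gamma_dot Shear rate in 1/s, within the measured range.
#' @return Viscosity in Pa.s.
#' @export
viscosity_at <- function(curve, gamma_dot) {
  validate_flow_curve(curve)
  g <- curve$shear_rate_1_per_s
  if (gamma_dot < min(g) || gamma_dot > max(g))
    stop("shear rate ", gamma_dot, " outside the measured range [",
         min(g), ", ", max(g), "]; refusing to extrapolate")
  exp(approx(log(g), log(curve$viscosity_Pa_s),
             xout = log(gamma_dot))$y)
}

#' Write / read a flow curve as CSV
#'
#' @param curve A `flow_curve`.
#' @param path Output path.
#' @return `write_flow_curve` returns `path` invisibly; `read_flow_curve`
#'   returns a validated `flow_curve`.
#' @export
write_flow_curve <- function(curve, path) {
  write.csv(as.data.frame(curve)[, c("shear_rate_1_per_s",
                                     "viscosity_Pa_s")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_curve
#' @export
read_flow_curve <- function(path) {
  x <- read.csv(path)
  validate_flow_curve(x)
  structure(x, class = c("flow_curve", "data.frame"))
}
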