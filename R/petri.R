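#' Simulate stopwatch observations of Petri-dish disintegration
#'
#' Emulates an operator timing structural break-up with a stopwatch: each
#' replicate observes the scenario's true endpoint plus an observation
#' latency drawn from a zero-mean truncated normal (symmetric truncation
#' at `trunc_sd` standard deviations, so the latency stays zero-mean).
#' Observations at or beyond the cap, and scenarios whose endpoint
#' exceeds the cap, are right-censored.
#'
#' @param scenario A `film_scenario` (any method; the packaged use is
#'   Petri-dish cells).
#' @param n_replicates Number of replicate observations (>= 1).
#' @param seed Integer seed.
#' @param latency_sd Observation-latency sd in seconds; defaults to the
#'   packaged replicate spread for the scenario's film/method cell.
#' @return List of [endpoint_result()]s with source
#'   `"simulated_observation"`.
#' @export
simulate_petri_observation <- function(scenario, n_replicates = 3,
                                       seed = scenario$seed,
                                       latency_sd = NULL) {
  stopifnot(inherits(scenario, "film_scenario"))
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop("n_replicates must be at least 1")
  n_replicates <- as.integer(n_replicates)
  sdl <- latency_sd %||% scenario$obs_sd
  if (scenario$censored) {
    return(replicate(n_replicates,
                     endpoint_result(NA_real_, TRUE, scenario$cap_s,
                                     "simulated_observation"),
                     simplify = FALSE))
  }
  if (is.null(sdl) || !is.finite(sdl) || sdl < 0)
    stop("latency_sd must be a non-negative number")
  trunc_sd <- odf_params()$petri$latency_truncation_sd
  set.seed(derive_seed(seed, 0L))
  lapply(seq_len(n_replicates), function(i) {
    lat <- if (sdl == 0) 0 else {
      repeat {
        z <- rnorm(1, 0, sdl)
        if (abs(z) <= trunc_sd * sdl) break
      }
      z
    }
    obs <- scenario$true_endpoint_s + lat
    if (obs >= scenario$cap_s)
      endpoint_result(NA_real_, TRUE, scenario$cap_s,
                      "simulated_observation")
    else
      endpoint_result(max(obs, 0), FALSE, scenario$cap_s,
                      "simulated_observation")
  })
}
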