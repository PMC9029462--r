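#' Construct a disintegration event
#'
#' Events script what happens to the film during a scenario. Supported
#' kinds:
#' \describe{
#'   \item{shrink}{Uniform scale loss toward the film centroid;
#'     `rate_per_s` is the fractional scale lost per second.}
#'   \item{swell}{Uniform growth to `factor` times the printed size over
#'     `ramp_s` seconds (hydration swelling).}
#'   \item{tear}{A strip of material removed along a cut line.
#'     `orientation` is `"vertical"` (cut at `at_frac` of the half-width,
#'     spanning `span_frac` of the height from the top edge) or `"corner"`
#'     (diagonal cut removing the bottom-right corner at depth `cut_px`).
#'     A full-span (`span_frac = 1`) vertical tear splits the film in two;
#'     partial tears reduce area but leave it connected.}
#'   \item{detach}{The portion of the film right of a cut line holding
#'     `area_fraction` of the area separates and translates away at
#'     `speed_mm_s` until it leaves the field of view.}
#'   \item{coalesce}{Reverses a prior tear or detach; `ref` is the index of
#'     the referenced event in the scenario's event list.}
#' }
#'
#' @param kind Event kind (see Details).
#' @param onset_s Onset time in seconds (non-negative).
#' @param ... Kind-specific parameters.
#' @return A `disintegration_event` list.
#' @export
disintegration_event <- function(kind = c("shrink", "tear", "detach",
                                          "coalesce", "swell"),
                                 onset_s, ...) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(onset_s), length(onset_s) == 1L, onset_s >= 0)
  params <- list(...)
  defaults <- switch(kind,
    shrink   = list(rate_per_s = 0.01),
    swell    = list(factor = 1.1, ramp_s = 60),
    tear     = list(orientation = "vertical", at_frac = 0, width_px = 3,
                    span_frac = 1, cut_px = 20),
    detach   = list(area_fraction = 0.2, speed_mm_s = 3),
    coalesce = list(ref = NA_integer_))
  ev <- modifyList(defaults, params)
  if (kind == "shrink" && ev$rate_per_s <= 0)
    stop("shrink rate_per_s must be positive")
  if (kind == "swell" && (ev$factor <= 0 || ev$ramp_s <= 0))
    stop("swell factor and ramp_s must be positive")
  if (kind == "detach" &&
      (ev$area_fraction <= 0 || ev$area_fraction >= 1))
    stop("detach area_fraction must lie in (0, 1)")
  if (kind == "tear" && (ev$span_frac <= 0 || ev$span_frac > 1))
    stop("tear span_frac must lie in (0, 1]")
  structure(c(list(kind = kind, onset_s = onset_s), ev),
            class = "disintegration_event")
}

ocm_events <- function(film_id, params) {
  arch <- params$ocm_archetypes[[film_id]]
  ev <- list()
  if (arch$kind == "detach_then_disintegrate") {
    onset <- params$endpoints[[film_id]]$ocm$mean
    ev <- c(ev, list(
      disintegration_event("detach", onset,
                           area_fraction = arch$detach_area_fraction,
                           speed_mm_s = arch$detach_speed_mm_s),
      disintegration_event("shrink", onset + arch$shrink_onset_after_s,
                           rate_per_s = arch$shrink_rate_per_s)))
  } else if (arch$kind == "transient_tears") {
    for (i in seq_along(arch$corner_tear_onsets_s)) {
      ev <- c(ev, list(
        disintegration_event("tear", arch$corner_tear_onsets_s[i],
                             orientation = "corner",
                             cut_px = arch$corner_cut_px)))
      ev <- c(ev, list(
        disintegration_event("coalesce", arch$corner_tear_coalesce_s[i],
                             ref = length(ev))))
    }
    ev <- c(ev, list(
      disintegration_event("tear", arch$long_tear_onset_s,
                           orientation = "vertical",
                           at_frac = arch$long_tear_at_frac,
                           span_frac = arch$long_tear_span_frac,
                           width_px = arch$long_tear_width_px %||% 3)))
    ev <- c(ev, list(
      disintegration_event("coalesce", arch$long_tear_coalesce_s,
                           ref = length(ev))))
  } else if (arch$kind == "swell_only") {
    ev <- c(ev, list(
      disintegration_event("swell", arch$swell_onset_s,
                           factor = arch$swell_factor,
                           ramp_s = arch$swell_ramp_s)))
  }
  ev
}

#' Build a packaged film x method scenario
#'
#' Assembles the ground-truth script for one film under one test method.
#' The scenario's `true_endpoint_s` is the packaged mean disintegration
#' time for that film/method cell; cells where no disintegration occurs
#' within the 180 s Pharmacopoeial cap are right-censored. The event
#' schedule follows the per-film archetypes: P1 in the oral cavity model
#' detaches a fragment at the endpoint then progressively disintegrates;
#' P2 suffers transient tears that later coalesce (no persistent split);
#' C1 and C2 only swell and adhere.
#'
#' @param film_id One of `"C1"`, `"C2"`, `"P1"`, `"P2"`.
#' @param method One of `"petri"`, `"ocm"`, `"btm"`.
#' @param overrides Optional named list of scenario fields to override
#'   (e.g. `duration_s`, `seed`, `events`, `cof_signature` members).
#' @return A `film_scenario` list with fields `film`, `method`,
#'   `duration_s`, `events`, `true_endpoint_s`, `censored`, `cap_s`,
#'   `obs_sd`, `cof_signature` (BTM only) and `seed`.
#' @export
build_scenario <- function(film_id, method, overrides = NULL) {
  p <- odf_params()
  film <- film_spec(film_id)  # validates film_id
  if (!is.character(method) || length(method) != 1L ||
      !method %in% odf_methods()) {
    stop("unknown method '", paste(method, collapse = ","),
         "'; expected one of: ", paste(odf_methods(), collapse = ", "))
  }
  cell <- p$endpoints[[film_id]][[method]]
  censored <- isTRUE(cell$censored)
  cap <- p$cap_s
  endpoint <- if (censored) NA_real_ else cell$mean
  obs_sd <- if (censored) NA_real_ else cell$sd

  events <- list()
  cof_signature <- NULL
  if (method == "ocm") {
    duration <- if (censored) cap else
      min(cap, endpoint + p$ocm$duration_margin_s)
    events <- ocm_events(film_id, p)
  } else if (method == "btm") {
    duration <- min(cap, endpoint + p$btm$duration_margin_s)
    sig <- as.list(p$cof_signatures[[film_id]])
    cof_signature <- c(sig, list(transition_s = endpoint))
    events <- list(disintegration_event("tear", endpoint,
                                        orientation = "vertical",
                                        at_frac = 0, span_frac = 1))
  } else {  # petri: stopwatch observation of structural break
    duration <- cap
    if (!censored)
      events <- list(disintegration_event("tear", endpoint,
                                          orientation = "vertical",
                                          at_frac = 0.1, span_frac = 1))
  }

  sc <- list(film = film, method = method, duration_s = duration,
             events = events, true_endpoint_s = endpoint,
             censored = censored, cap_s = cap, obs_sd = obs_sd,
             cof_signature = cof_signature, seed = 1L)
  if (!is.null(overrides)) {
    if (!is.list(overrides) || is.null(names(overrides)) ||
        any(names(overrides) == ""))
      stop("overrides must be a named list")
    unknown <- setdiff(names(overrides), names(sc))
    if (length(unknown))
      stop("unknown scenario override(s): ", paste(unknown, collapse = ", "))
    if (!is.null(overrides$cof_signature))
      overrides$cof_signature <- modifyList(sc$cof_signature %||% list(),
                                            overrides$cof_signature)
    for (nm in names(overrides)) sc[[nm]] <- overrides[[nm]]
  }
  validate_scenario(structure(sc, class = "film_scenario"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "film_scenario"))
  if (!is.numeric(sc$duration_s) || sc$duration_s <= 0)
    stop("duration_s must be positive")
  onsets <- vapply(sc$events, `[[`, numeric(1), "onset_s")
  if (is.unsorted(onsets))
    stop("events must be ordered by onset time")
  if (length(onsets) && any(onsets >= sc$duration_s + 1e-9) && !sc$censored)
    stop("event onset beyond scenario duration")
  if (!sc$censored) {
    if (!is.finite(sc$true_endpoint_s) || sc$true_endpoint_s <= 0)
      stop("true_endpoint_s must be positive for non-censored scenarios")
    if (sc$true_endpoint_s > sc$duration_s + 1e-9)
      stop("true_endpoint_s exceeds duration_s")
  }
  if (sc$method == "btm" && is.null(sc$cof_signature))
    stop("BTM scenarios require a cof_signature")
  if (sc$method != "btm" && !is.null(sc$cof_signature))
    stop("cof_signature only applies to BTM scenarios")
  if (!is.null(sc$cof_signature)) {
    sig <- sc$cof_signature
    stopifnot(sig$mu_initial > 0, sig$mu_initial < 1.5,
              sig$mu_plateau > 0, sig$mu_plateau < 1.5)
    if (identical(sig$shape, "decline_plateau") &&
        sig$mu_plateau >= sig$mu_initial)
      stop("decline_plateau signature requires mu_plateau < mu_initial")
    if (!is.finite(sig$transition_s) || sig$transition_s <= 0 ||
        sig$transition_s >= sc$duration_s)
      stop("cof signature transition_s must lie inside the scenario duration")
  }
  # a coalesce event must reference a prior tear or detach
  for (i in seq_along(sc$events)) {
    ev <- sc$events[[i]]
    if (ev$kind == "coalesce") {
      if (is.na(ev$ref) || ev$ref < 1 || ev$ref >= i ||
          !sc$events[[ev$ref]]$kind %in% c("tear", "detach"))
        stop("coalesce event must reference a prior tear/detach event")
      if (sc$events[[ev$ref]]$onset_s >= ev$onset_s)
        stop("coalesce must follow the event it reverses")
    }
  }
  sc
}

#' @export
print.film_scenario <- function(x, ...) {
  ep <- if (x$censored) sprintf(">%.1f (censored)", x$cap_s)
        else sprintf("%.1f s", x$true_endpoint_s)
  cat(sprintf("<film_scenario %s / %s: duration %.1f s, endpoint %s, %d event(s)%s>\n",
              x$film$film_id, x$method, x$duration_s, ep, length(x$events),
              if (!is.null(x$cof_signature))
                sprintf(", CoF %s", x$cof_signature$shape) else ""))
  invisible(x)
}

#' Write / read a scenario as JSON
#'
#' @param scenario A `film_scenario`.
#' @param path Output path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns a validated `film_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "film_scenario"))
  sc <- unclass(scenario)
  sc$film <- unclass(sc$film)
  sc$events <- lapply(sc$events, unclass)
  jsonlite::write_json(sc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  sc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sc$film <- structure(sc$film, class = "film_spec")
  sc$events <- lapply(seq_len(nrow(sc$events %||% data.frame())),
                      function(i) {
    ev <- as.list(sc$events[i, ])
    ev <- ev[!vapply(ev, function(v) is.na(v) || is.null(v), logical(1)) |
               names(ev) %in% c("kind", "onset_s")]
    structure(ev, class = "disintegration_event")
  })
  if (!is.null(sc$true_endpoint_s) && is.null(sc$true_endpoint_s))
    sc$true_endpoint_s <- NA_real_
  sc$true_endpoint_s <- sc$true_endpoint_s %||% NA_real_
  sc$obs_sd <- sc$obs_sd %||% NA_real_
  validate_scenario(structure(sc, class = "film_scenario"))
}
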