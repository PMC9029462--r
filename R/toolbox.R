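#' End-to-end toolbox configuration
#'
#' Defaults are the packaged study conditions: all four films, all three
#' methods, three replicates, the 180 s Pharmacopoeial cap and 30 fps
#' video. Tests and exploratory runs can scale `fps` and `cap_s` down;
#' censoring semantics are preserved at any cap.
#'
#' @param films Film ids to run.
#' @param methods Methods to run.
#' @param n_replicates Replicates per film x method cell.
#' @param seed Global seed; per-replicate seeds are derived as
#'   `seed + replicate index` offset by a fixed per-cell stride.
#' @param fps Analysis frame rate for rendered video.
#' @param cap_s Censoring cap in seconds.
#' @param persistence_frames Video endpoint persistence rule.
#' @param rep_mu_jitter_sd Per-replicate random offset applied to the
#'   friction signature levels, emulating specimen-to-specimen
#'   variability so replicate-level statistics are non-degenerate.
#' @param petri_latency_sd Override for the Petri observation latency sd
#'   (default: packaged per-film spread).
#' @return A `toolbox_config` list.
#' @export
toolbox_config <- function(films = film_ids(), methods = odf_methods(),
                           n_replicates = 3, seed = 1, fps = 30,
                           cap_s = 180, persistence_frames = 5,
                           rep_mu_jitter_sd = 0.015,
                           petri_latency_sd = NULL) {
  stopifnot(length(films) >= 1, length(methods) >= 1, n_replicates >= 1,
            fps > 0, cap_s > 0)
  if (!all(films %in% film_ids()))
    stop("unknown film id(s): ",
         paste(setdiff(films, film_ids()), collapse = ", "))
  if (!all(methods %in% odf_methods()))
    stop("unknown method(s): ",
         paste(setdiff(methods, odf_methods()), collapse = ", "))
  structure(list(films = films, methods = methods,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), fps = fps, cap_s = cap_s,
                 persistence_frames = persistence_frames,
                 rep_mu_jitter_sd = rep_mu_jitter_sd,
                 petri_latency_sd = petri_latency_sd),
            class = "toolbox_config")
}

# polynomial rolling hash of the deparsed config, for provenance stamping
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

run_cell_replicate <- function(film, method, rep, config) {
  rep_seed <- derive_seed(config$seed + rep,
                          match(film, film_ids()) * 3 +
                            match(method, odf_methods()))
  sc <- build_scenario(film, method)
  if (method == "petri") {
    obs <- simulate_petri_observation(sc, 1, seed = rep_seed,
                                      latency_sd = config$petri_latency_sd)[[1]]
    if (!obs$censored && obs$time_s >= config$cap_s)
      obs <- endpoint_result(NA_real_, TRUE, config$cap_s,
                             "simulated_observation")
    return(list(endpoint = obs, mean_cof = NA_real_, profile = NULL))
  }
  if (method == "ocm") {
    dur <- min(sc$duration_s, config$cap_s)
    frames <- render_video(sc, seed = rep_seed, fps = config$fps,
                           duration_s = dur)
    prof <- extract_profile(frames)
    ep <- detect_endpoint(prof, config$persistence_frames, config$cap_s)
    return(list(endpoint = ep, mean_cof = NA_real_, profile = prof))
  }
  # btm: friction trace -> per-stroke CoF -> change-point endpoint
  jit <- 0
  if (config$rep_mu_jitter_sd > 0) {
    set.seed(derive_seed(rep_seed, 99L))
    jit <- rnorm(1, 0, config$rep_mu_jitter_sd)
  }
  sig <- sc$cof_signature
  sig$mu_initial <- sig$mu_initial + jit
  sig$mu_plateau <- sig$mu_plateau + jit
  sc2 <- build_scenario(film, method,
                        overrides = list(cof_signature = sig,
                                         seed = rep_seed))
  trace <- synth_friction_trace(sc2, seed = rep_seed)
  series <- compute_cof(trace)
  ep <- detect_friction_endpoint(series, cap_s = config$cap_s)
  list(endpoint = ep, mean_cof = mean_cof(series), profile = NULL,
       cof_series = series)
}

#' Run the full in vitro toolbox on synthetic scenarios
#'
#' For every requested film x method x replicate: generate the scenario
#' data with the matching generator, run the matching analysis (simulated
#' stopwatch observation for Petri, video profiling for the oral cavity
#' model, friction trace + change-point detection for the BioTribometer),
#' then aggregate endpoints per cell with censoring notation, summarise
#' mean coefficient of friction per film, and run one-way ANOVA with
#' Tukey's test on replicate-level mean CoF and on non-censored Petri
#' endpoints. A failing cell replicate is recorded as failed with its
#' error message; the run continues. Deterministic given the config seed.
#'
#' @param config A [toolbox_config()].
#' @return A `toolbox_summary` list: `endpoints` (one row per cell:
#'   mean, sd, n observed, n censored, rendered label), `replicates`
#'   (per-replicate rows), `mean_cof` (per film), `stats`
#'   (`group_stats` blocks), `profiles` (OCM profiles, keyed
#'   `film.replicate`), `provenance`.
#' @export
run_toolbox <- function(config = toolbox_config()) {
  stopifnot(inherits(config, "toolbox_config"))
  reps <- list(); profiles <- list()
  for (film in config$films) for (method in config$methods) {
    for (r in seq_len(config$n_replicates)) {
      res <- tryCatch(run_cell_replicate(film, method, r, config),
                      error = function(e)
                        list(failed = conditionMessage(e)))
      if (!is.null(res$failed)) {
        reps[[length(reps) + 1L]] <- data.frame(
          film = film, method = method, replicate = r,
          time_s = NA_real_, censored = NA, mean_cof = NA_real_,
          failed = res$failed)
        next
      }
      ep <- res$endpoint
      reps[[length(reps) + 1L]] <- data.frame(
        film = film, method = method, replicate = r,
        time_s = if (ep$censored) NA_real_ else ep$time_s,
        censored = ep$censored, mean_cof = res$mean_cof,
        failed = NA_character_)
      if (!is.null(res$profile))
        profiles[[paste(film, r, sep = ".")]] <- res$profile
    }
  }
  replicates <- do.call(rbind, reps)

  cells <- unique(replicates[, c("film", "method")])
  endpoints <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- replicates[replicates$film == cells$film[i] &
                        replicates$method == cells$method[i], ]
    fail <- sum(!is.na(sub$failed))
    obs <- sub$time_s[!is.na(sub$censored) & !sub$censored]
    cen <- sum(sub$censored, na.rm = TRUE)
    all_cen <- length(obs) == 0 && cen > 0
    m <- if (length(obs)) mean(obs) else NA_real_
    s <- if (length(obs) >= 2) sd(obs) else NA_real_
    label <- if (all_cen) sprintf(">%.1f", config$cap_s)
             else if (length(obs) >= 2) sprintf("%.1f ± %.1f", m, s)
             else if (length(obs) == 1) sprintf("%.1f (n = 1)", m)
             else "failed"
    data.frame(film = cells$film[i], method = cells$method[i],
               mean_s = m, sd_s = s, n_observed = length(obs),
               n_censored = cen, n_failed = fail, label = label)
  }))

  cof <- NULL
  if ("btm" %in% config$methods) {
    sub <- replicates[replicates$method == "btm" &
                        !is.na(replicates$mean_cof), ]
    if (nrow(sub)) {
      cof <- do.call(rbind, lapply(split(sub, sub$film), function(g)
        data.frame(film = g$film[1], mean_cof = mean(g$mean_cof),
                   sd_cof = if (nrow(g) >= 2) sd(g$mean_cof) else NA_real_,
                   n = nrow(g))))
      rownames(cof) <- NULL
      cof <- cof[order(match(cof$film, config$films)), ]
    }
  }

  stats <- list()
  if (!is.null(cof)) {
    groups <- split(replicates$mean_cof[replicates$method == "btm"],
                    replicates$film[replicates$method == "btm"])
    groups <- lapply(groups, function(v) v[!is.na(v)])
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) >= 2)
      stats$mean_cof <- compare_groups(groups)
  }
  if ("petri" %in% config$methods) {
    sub <- replicates[replicates$method == "petri" &
                        !is.na(replicates$censored) & !replicates$censored, ]
    groups <- split(sub$time_s, sub$film)
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) >= 2)
      stats$petri_endpoint <- compare_groups(groups)
  }

  structure(list(endpoints = endpoints, replicates = replicates,
                 mean_cof = cof, stats = stats, profiles = profiles,
                 provenance = list(seed = config$seed,
                                   config_hash = config_hash(config),
                                   package_version =
                                     as.character(utils::packageVersion("odftoolbox")))),
            class = "toolbox_summary")
}

#' @export
print.toolbox_summary <- function(x, ...) {
  cat("In vitro ODF toolbox summary (disintegration time, s)\n")
  wide <- tapply(x$endpoints$label,
                 list(x$endpoints$film, x$endpoints$method),
                 identity)
  print(wide, quote = FALSE)
  if (!is.null(x$mean_cof)) {
    cat("\nMean coefficient of friction:\n")
    print(x$mean_cof, row.names = FALSE)
  }
  for (nm in names(x$stats)) {
    s <- x$stats[[nm]]
    cat(sprintf("\n%s: one-way ANOVA F = %.4g, p = %.3g\n",
                nm, s$anova_F, s$anova_p))
  }
  cat(sprintf("\nprovenance: seed %d, config %s\n",
              x$provenance$seed, x$provenance$config_hash))
  invisible(x)
}

#' Serialise a toolbox summary to JSON
#'
#' Output is byte-identical across reruns with identical config and
#' seeds.
#'
#' @param summary A `toolbox_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  out <- list(endpoints = summary$endpoints,
              replicates = summary$replicates,
              mean_cof = summary$mean_cof,
              stats = lapply(summary$stats, function(s)
                list(means = as.list(s$means), sds = as.list(s$sds),
                     anova_F = s$anova_F, anova_p = s$anova_p,
                     tukey = s$tukey)),
              provenance = summary$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Plot mean disintegration profiles and CoF series
#'
#' Writes one mean +/- sd area-fraction profile plot per film (replicate
#' profiles aligned on time) and, when CoF series are supplied, a
#' CoF-time plot. Returns the averaged series so callers can assert on
#' the plotted data rather than on image files.
#'
#' @param profiles Named list of `disintegration_profile`s; names are
#'   `film.replicate` as produced by [run_toolbox()].
#' @param out_dir Output directory for PNG files.
#' @param cof_series Optional named list of `cof_series` keyed the same
#'   way.
#' @return Invisibly, a list with per-film averaged `area` (t_s, mean,
#'   sd) and `cof` data frames.
#' @export
render_profiles <- function(profiles, out_dir, cof_series = NULL) {
  if (length(profiles) == 0 && length(cof_series) == 0)
    stop("empty profile list")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  films <- unique(sub("\\..*$", "", names(profiles)))
  averaged <- list()
  for (film in films) {
    ps <- profiles[grep(paste0("^", film, "\\."), names(profiles))]
    nmin <- min(vapply(ps, nrow, integer(1)))
    t_s <- ps[[1]]$t_s[seq_len(nmin)]
    af <- vapply(ps, function(p) p$area_fraction[seq_len(nmin)],
                 numeric(nmin))
    af <- matrix(af, nrow = nmin)
    m <- rowMeans(af)
    s <- if (ncol(af) >= 2) apply(af, 1, sd) else rep(0, nmin)
    averaged[[film]]$area <- data.frame(t_s = t_s, mean = m, sd = s)
    f <- file.path(out_dir, sprintf("profile_%s.png", film))
    grDevices::png(f, width = 900, height = 600)
    plot(t_s, m, type = "l", lwd = 2, ylim = c(0, max(1.2, m + s)),
         xlab = "time (s)", ylab = "area fraction",
         main = sprintf("%s mean disintegration profile (n = %d)",
                        film, ncol(af)))
    graphics::polygon(c(t_s, rev(t_s)), c(m - s, rev(m + s)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(t_s, m, lwd = 2)
    grDevices::dev.off()
  }
  if (!is.null(cof_series) && length(cof_series)) {
    f <- file.path(out_dir, "cof_time.png")
    grDevices::png(f, width = 900, height = 600)
    cols <- grDevices::hcl.colors(length(cof_series), "Dark 2")
    xmax <- max(vapply(cof_series, function(s) max(s$t_mid_s),
                       numeric(1)))
    ymax <- max(vapply(cof_series, function(s) max(s$mu, na.rm = TRUE),
                       numeric(1)))
    plot(NULL, xlim = c(0, xmax), ylim = c(0, ymax * 1.1),
         xlab = "time (s)", ylab = "coefficient of friction",
         main = "Per-stroke coefficient of friction")
    for (i in seq_along(cof_series))
      graphics::lines(cof_series[[i]]$t_mid_s, cof_series[[i]]$mu,
                      col = cols[i], lwd = 2)
    graphics::legend("topright", legend = names(cof_series), col = cols,
                     lwd = 2, bty = "n")
    grDevices::dev.off()
    averaged$cof <- cof_series
  }
  invisible(averaged)
}
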