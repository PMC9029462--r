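# Ground-truth geometry -------------------------------------------------
#
# The film is a rounded-corner rectangle rasterised analytically per frame:
# a pixel (x, y) is film iff the clamped distances to the shrunken core
# rectangle satisfy dx^2 + dy^2 <= r^2. Scaling the half-dimensions and
# corner radius by a common factor nests the rasterised sets, so shrink
# schedules yield pixel-monotone masks by construction.

film_scale_at <- function(events, t) {
  s <- 1
  for (ev in events) {
    if (ev$kind == "shrink" && t >= ev$onset_s)
      s <- s - ev$rate_per_s * (t - ev$onset_s)
    if (ev$kind == "swell" && t >= ev$onset_s) {
      frac <- min(1, (t - ev$onset_s) / ev$ramp_s)
      s <- s * (1 + (ev$factor - 1) * frac)
    }
  }
  max(s, 0.05)
}

coalesce_time <- function(events, idx) {
  for (j in seq_along(events)) {
    ev <- events[[j]]
    if (ev$kind == "coalesce" && !is.na(ev$ref) && ev$ref == idx)
      return(ev$onset_s)
  }
  Inf
}

rounded_rect_mask <- function(xs, ys, cx, cy, a, b, r) {
  dx <- pmax(abs(xs - cx) - (a - r), 0)
  dy <- pmax(abs(ys - cy) - (b - r), 0)
  outer(dy^2, dx^2, "+") <= r^2
}

#' Ground-truth film mask at a given time
#'
#' Rasterises the scenario's scripted geometry at time `t`: base rounded
#' rectangle at the current shrink/swell scale, minus active tear strips,
#' with detached fragments translated by their elapsed travel. This is the
#' generator's ground truth; the video profiler never sees it except
#' through rendered frames.
#'
#' @param scenario A `film_scenario`.
#' @param t Time in seconds.
#' @param geom Optional precomputed geometry (internal).
#' @return Logical matrix (rows = y, cols = x).
#' @export
scenario_mask <- function(scenario, t, geom = NULL) {
  if (is.null(geom)) geom <- video_geometry(scenario)
  v <- geom
  s <- film_scale_at(scenario$events, t)
  a <- v$a0 * s; b <- v$b0 * s; r <- v$r0 * s
  mask <- rounded_rect_mask(v$xs, v$ys, v$cx, v$cy, a, b, r)

  events <- scenario$events
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (ev$kind == "tear" && t >= ev$onset_s &&
        t < coalesce_time(events, i)) {
      if (identical(ev$orientation, "corner")) {
        # diagonal strip cutting off the bottom-right corner
        cc <- (v$cx + a) + (v$cy + b) - ev$cut_px
        diag_pos <- outer(v$ys, v$xs, "+")
        mask[diag_pos >= cc & diag_pos < cc + ev$width_px] <- FALSE
      } else {
        x0 <- v$cx + ev$at_frac * a
        ylim <- v$cy - b + ev$span_frac * 2 * b
        strip <- outer(v$ys <= ylim, v$xs >= x0 & v$xs < x0 + ev$width_px,
                       "&")
        mask[strip] <- FALSE
      }
    }
    if (ev$kind == "detach" && t >= ev$onset_s) {
      xcut <- v$cx + a * (1 - 2 * ev$area_fraction)
      shift <- (ev$speed_mm_s / v$mm_per_px) * (t - ev$onset_s)
      gap <- 3
      # main remnant: keep everything left of the cut (minus a small kerf)
      mask[, v$xs > xcut - gap] <- FALSE
      if (t < coalesce_time(events, i)) {
        frag <- rounded_rect_mask(v$xs, v$ys, v$cx + shift, v$cy, a, b, r)
        frag[, v$xs - shift <= xcut] <- FALSE
        mask <- mask | frag
      }
    }
  }
  mask
}

video_geometry <- function(scenario, fps = NULL) {
  v <- odf_params()$video
  w <- v$width_px; h <- v$height_px
  mm <- v$mm_per_px
  list(width = w, height = h, mm_per_px = mm,
       fps = fps %||% v$fps,
       xs = seq_len(w), ys = seq_len(h),
       cx = w / 2, cy = h / 2,
       a0 = scenario$film$width_mm / mm / 2,
       b0 = scenario$film$height_mm / mm / 2,
       r0 = v$corner_radius_mm / mm,
       film_rgb = v$film_rgb, background_rgb = v$background_rgb,
       noise_sd = v$noise_sd,
       band_hw = v$btm_band_halfwidth_px,
       band_amp = v$btm_band_amplitude,
       band_sweep = v$btm_band_sweep_px)
}

#' Render a synthetic plan-view disintegration video
#'
#' Realises a scenario's scripted geometry as an RGB frame sequence with
#' per-frame ground-truth masks. The dyed film is rendered saturated
#' magenta on a pale silicone-tone background with per-frame Gaussian
#' appearance noise. Method-specific artifacts are injected: the oral
#' cavity model dims frames during the periodic 2 s compression phase, the
#' BioTribometer sweeps an additive specular band across the image at the
#' 1 Hz reciprocation frequency.
#'
#' Frames are generated lazily (`$frame(i)`, `$mask(i)`) so long videos
#' never materialise in memory; identical `(scenario, seed)` pairs yield
#' bit-identical frames.
#'
#' @param scenario A `film_scenario`.
#' @param seed Integer seed controlling appearance noise.
#' @param fps Frames per second (default: packaged 30).
#' @param duration_s Optional rendering duration cap (default: scenario
#'   duration).
#' @return A `frame_sequence` with elements `n_frames`, `fps`,
#'   `mm_per_px`, `width`, `height`, `frame(i)` (h x w x 3 array with
#'   values in 0..1), `mask(i)` (logical ground-truth raster),
#'   `scenario`, `seed`.
#' @export
render_video <- function(scenario, seed = scenario$seed, fps = NULL,
                         duration_s = NULL) {
  stopifnot(inherits(scenario, "film_scenario"))
  geom <- video_geometry(scenario, fps)
  if (!is.numeric(geom$fps) || geom$fps <= 0) stop("fps must be positive")
  dur <- duration_s %||% scenario$duration_s
  n <- max(2L, as.integer(round(dur * geom$fps)))
  frame_seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i),
                        integer(1))
  t_of <- function(i) (i - 1) / geom$fps

  mask_fun <- function(i) {
    stopifnot(i >= 1, i <= n)
    scenario_mask(scenario, t_of(i), geom)
  }
  h <- geom$height; w <- geom$width; npx <- h * w
  oc <- odf_params()$ocm
  btm_freq <- odf_params()$btm$frequency_hz
  frame_fun <- function(i) {
    stopifnot(i >= 1, i <= n)
    t <- t_of(i)
    m <- scenario_mask(scenario, t, geom)
    bright <- 1
    if (scenario$method == "ocm" &&
        (t %% oc$compression_period_s) < oc$compression_duration_s)
      bright <- oc$compression_brightness
    band_lo <- -1L; band_hi <- -1L; band_amp <- 0
    if (scenario$method == "btm") {
      yc <- h / 2 + geom$band_sweep * sin(2 * pi * btm_freq * t)
      band_lo <- as.integer(ceiling(yc - geom$band_hw)) - 1L
      band_hi <- as.integer(floor(yc + geom$band_hw)) - 1L
      band_amp <- geom$band_amp
    }
    set.seed(frame_seeds[i])
    noise <- rnorm(npx, 0, geom$noise_sd)  # shared luminance noise
    compose_frame(m, geom$background_rgb, geom$film_rgb, bright,
                  band_lo, band_hi, band_amp, noise)
  }

  structure(list(n_frames = n, fps = geom$fps, mm_per_px = geom$mm_per_px,
                 width = geom$width, height = geom$height,
                 frame = frame_fun, mask = mask_fun,
                 scenario = scenario, seed = seed),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) x$n_frames

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence %s/%s: %d frames @ %g fps, %dx%d px, seed %d>\n",
              x$scenario$film$film_id, x$scenario$method, x$n_frames,
              x$fps, x$width, x$height, x$seed))
  invisible(x)
}

#' Write a frame sequence to a PNG directory
#'
#' @param frames A `frame_sequence`.
#' @param dir Output directory (created if missing).
#' @param indices Frame indices to write (default: all).
#' @param masks Also write ground-truth masks as single-channel PNGs.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir, indices = seq_len(frames$n_frames),
                         masks = FALSE) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write frames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in indices) {
    p <- file.path(dir, sprintf("frame_%05d.png", i))
    png::writePNG(frames$frame(i), p)
    paths <- c(paths, p)
    if (masks) {
      pm <- file.path(dir, sprintf("mask_%05d.png", i))
      png::writePNG(frames$mask(i) * 1, pm)
      paths <- c(paths, pm)
    }
  }
  invisible(paths)
}

#' Read a directory of PNG frames as a frame sequence
#'
#' @param dir Directory holding `frame_*.png` files (written by
#'   [write_frames()] or any tool producing the same layout).
#' @param fps Frame rate of the sequence.
#' @param mm_per_px Optional spatial calibration.
#' @return A `frame_sequence` without ground-truth masks.
#' @export
read_frames <- function(dir, fps = 30, mm_per_px = NA_real_) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read frames")
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame_*.png files in ", dir)
  first <- png::readPNG(files[[1]])
  structure(list(n_frames = length(files), fps = fps,
                 mm_per_px = mm_per_px,
                 width = dim(first)[2], height = dim(first)[1],
                 frame = function(i) png::readPNG(files[[i]]),
                 mask = function(i) stop("no ground-truth masks available"),
                 scenario = NULL, seed = NA_integer_),
            class = "frame_sequence")
}
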