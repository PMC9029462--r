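#' Measure one binary frame mask
#'
#' Fragments are 8-connected components with at least `min_fragment_px`
#' pixels. `area_px` sums the retained component areas;
#' `perimeter_px` is the total outer-contour length of the retained
#' components, where each contour is the closed polygon through
#' boundary-pixel centres (unit steps for 4-neighbour moves, sqrt(2) for
#' diagonals; a filled 10 x 10 square therefore has perimeter 36).
#'
#' @param mask Logical matrix.
#' @param min_fragment_px Minimum component area retained as a fragment.
#' @param t_s Optional timestamp carried into the result row.
#' @return One-row data frame: `t_s`, `area_px`, `perimeter_px`,
#'   `n_fragments`, `largest_fragment_area_px`.
#' @export
measure_frame <- function(mask, min_fragment_px = 0, t_s = NA_real_) {
  stopifnot(is.matrix(mask))
  lab <- cc_label8(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  nlab <- attr(lab, "n_labels")
  if (nlab == 0L) {
    return(data.frame(t_s = t_s, area_px = 0L, perimeter_px = 0,
                      n_fragments = 0L, largest_fragment_area_px = 0L))
  }
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- areas >= max(1, min_fragment_px)
  if (!any(keep)) {
    return(data.frame(t_s = t_s, area_px = 0L, perimeter_px = 0,
                      n_fragments = 0L, largest_fragment_area_px = 0L))
  }
  per <- contour_perimeter(lab, nlab)
  data.frame(t_s = t_s,
             area_px = as.integer(sum(areas[keep])),
             perimeter_px = sum(per[keep]),
             n_fragments = as.integer(sum(keep)),
             largest_fragment_area_px = as.integer(max(areas[keep])))
}

#' Profile-extraction configuration
#'
#' @param segmentation A [segmentation_config()].
#' @param min_fragment_frac Minimum fragment size as a fraction of the
#'   segmented film area at t = 0 (default 0.005).
#' @param median_window Temporal median-filter window (odd number of
#'   frames) applied to area and perimeter to suppress compression
#'   artifacts; 1 disables.
#' @param decompressed_only For oral-cavity-model footage, restrict
#'   analysis to decompressed-phase frames (the portion of each 2 s
#'   compression cycle after the compression artifact has passed).
#' @return A `profile_config` list.
#' @export
profile_config <- function(segmentation = segmentation_config(),
                           min_fragment_frac = 0.005,
                           median_window = 7,
                           decompressed_only = FALSE) {
  stopifnot(min_fragment_frac >= 0, min_fragment_frac < 1,
            median_window >= 1, median_window %% 2 == 1)
  structure(list(segmentation = segmentation,
                 min_fragment_frac = min_fragment_frac,
                 median_window = median_window,
                 decompressed_only = decompressed_only),
            class = "profile_config")
}

#' Extract a disintegration-time profile from a frame sequence
#'
#' Segments every analysed frame, measures fragment area, perimeter and
#' count, and normalises area to the first frame (area fraction 1 at
#' t = 0 by construction). Area and perimeter are optionally median
#' filtered in time; the raw fragment count is kept untouched because the
#' endpoint detector applies its own persistence rule.
#'
#' @param frames A `frame_sequence`.
#' @param config A [profile_config()].
#' @return A `disintegration_profile` data frame with columns `t_s`,
#'   `area_px`, `area_fraction`, `perimeter_px`, `n_fragments`,
#'   `largest_fragment_area_px`, and attributes `film_id`, `method`,
#'   `fps`, `min_fragment_px`, `mm_per_px`.
#' @export
extract_profile <- function(frames, config = profile_config()) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (frames$n_frames < 2) stop("need at least 2 frames")
  idx <- seq_len(frames$n_frames)
  t_s <- (idx - 1) / frames$fps
  if (isTRUE(config$decompressed_only) &&
      !is.null(frames$scenario) && frames$scenario$method == "ocm") {
    oc <- odf_params()$ocm
    keep <- (t_s %% oc$compression_period_s) >= oc$compression_duration_s
    keep[1] <- TRUE  # always anchor the normalisation frame
    idx <- idx[keep]; t_s <- t_s[keep]
  }
  first_mask <- segment_frame(frames$frame(idx[1]), config$segmentation)
  area0 <- sum(first_mask)
  if (area0 == 0) stop("no film detected at t = 0")
  min_px <- ceiling(config$min_fragment_frac * area0)

  rows <- vector("list", length(idx))
  rows[[1]] <- measure_frame(first_mask, min_px, t_s[1])
  for (k in seq_along(idx)[-1]) {
    m <- segment_frame(frames$frame(idx[k]), config$segmentation)
    rows[[k]] <- measure_frame(m, min_px, t_s[k])
  }
  prof <- do.call(rbind, rows)
  w <- min(config$median_window,
           if (nrow(prof) %% 2 == 0) nrow(prof) - 1 else nrow(prof))
  if (w >= 3) {
    prof$area_px <- as.integer(stats::runmed(prof$area_px, w,
                                             endrule = "keep"))
    prof$perimeter_px <- as.numeric(stats::runmed(prof$perimeter_px, w,
                                                  endrule = "keep"))
  }
  prof$area_fraction <- prof$area_px / prof$area_px[1]
  prof <- prof[, c("t_s", "area_px", "area_fraction", "perimeter_px",
                   "n_fragments", "largest_fragment_area_px")]
  structure(prof,
            class = c("disintegration_profile", "data.frame"),
            film_id = if (!is.null(frames$scenario))
              frames$scenario$film$film_id else NA_character_,
            method = if (!is.null(frames$scenario))
              frames$scenario$method else NA_character_,
            fps = frames$fps, min_fragment_px = min_px,
            mm_per_px = frames$mm_per_px)
}

#' Construct an endpoint result
#'
#' @param time_s Detected time in seconds, or `NA` when censored.
#' @param censored Logical; right-censored at `cap_s`.
#' @param cap_s Censoring cap in seconds (Pharmacopoeial limit 180).
#' @param source One of `"video_split"`, `"friction_changepoint"`,
#'   `"simulated_observation"`.
#' @return An `endpoint_result` list.
#' @export
endpoint_result <- function(time_s, censored, cap_s = 180,
                            source = c("video_split",
                                       "friction_changepoint",
                                       "simulated_observation")) {
  source <- match.arg(source)
  stopifnot(is.logical(censored), length(censored) == 1L, cap_s > 0)
  if (censored) time_s <- NA_real_
  if (!censored && (!is.finite(time_s) || time_s > cap_s + 1e-9))
    stop("non-censored endpoint must be finite and <= cap_s")
  structure(list(time_s = time_s, censored = censored, cap_s = cap_s,
                 source = source),
            class = "endpoint_result")
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat(if (x$censored) sprintf("<endpoint >%.1f s (censored, %s)>\n",
                              x$cap_s, x$source)
      else sprintf("<endpoint %.3f s (%s)>\n", x$time_s, x$source))
  invisible(x)
}

#' Detect the disintegration endpoint from a video profile
#'
#' Disintegration is the moment the film splits from one structure into
#' two distinct objects. The endpoint is the earliest time at which the
#' retained fragment count is at least `min_fragments` for
#' `persistence_frames` consecutive analysed frames; the persistence rule
#' prevents transient tears that later re-coalesce (the P2 behaviour)
#' from registering as disintegration. If no persistent split occurs
#' before `cap_s` the result is right-censored.
#'
#' @param profile A `disintegration_profile`.
#' @param persistence_frames Consecutive frames the split must persist.
#' @param cap_s Censoring cap in seconds.
#' @param min_fragments Fragment count that constitutes a split.
#' @return An [endpoint_result()] with source `"video_split"`.
#' @export
detect_endpoint <- function(profile, persistence_frames = 5, cap_s = 180,
                            min_fragments = 2) {
  stopifnot(inherits(profile, "disintegration_profile"),
            persistence_frames >= 1, cap_s > 0)
  if (nrow(profile) == 0) stop("empty profile")
  split <- profile$n_fragments >= min_fragments & profile$t_s <= cap_s
  r <- rle(split)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= persistence_frames)
  if (length(hit) == 0)
    return(endpoint_result(NA_real_, TRUE, cap_s, "video_split"))
  endpoint_result(profile$t_s[starts[hit[1]]], FALSE, cap_s, "video_split")
}

#' Write / read a disintegration profile as CSV
#'
#' @param profile A `disintegration_profile`.
#' @param path Output path.
#' @return `write_profile` returns `path` invisibly; `read_profile`
#'   returns the profile data frame.
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  prof <- read.csv(path)
  structure(prof, class = c("disintegration_profile", "data.frame"))
}

#' Write / read an endpoint result as JSON
#'
#' @param endpoint An `endpoint_result`.
#' @param path Output path.
#' @return `write_endpoint` returns `path` invisibly; `read_endpoint`
#'   returns the `endpoint_result`.
#' @export
write_endpoint <- function(endpoint, path) {
  jsonlite::write_json(unclass(endpoint), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_endpoint
#' @export
read_endpoint <- function(path) {
  x <- jsonlite::fromJSON(path)
  endpoint_result(x$time_s %||% NA_real_, x$censored, x$cap_s, x$source)
}
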