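#' Segmentation configuration
#'
#' The film is dyed pink, so the primary segmentation is a chromaticity
#' threshold on the red-minus-green excess, which is insensitive to the
#' brightness changes injected by the oral-cavity-model compression phase
#' and largely insensitive to additive specular highlights. A
#' gradient-based edge mode is retained as a fallback for footage where
#' the dye contrast is unreliable.
#'
#' @param mode `"chroma"` (default) or `"edge"`.
#' @param threshold Red-minus-green excess above which a pixel is film
#'   (chroma mode). Ignored when `auto_threshold = TRUE`.
#' @param auto_threshold Use Otsu's method on the chromaticity image
#'   instead of the fixed threshold.
#' @param opening_px Side of the square structuring element used for
#'   morphological opening (speck removal); 0 disables.
#' @param fill_holes Fill interior holes after thresholding.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(mode = c("chroma", "edge"),
                                threshold = 0.25,
                                auto_threshold = FALSE,
                                opening_px = 3,
                                fill_holes = TRUE) {
  mode <- match.arg(mode)
  stopifnot(threshold > -1, threshold < 1, opening_px >= 0)
  structure(list(mode = mode, threshold = threshold,
                 auto_threshold = auto_threshold,
                 opening_px = opening_px, fill_holes = fill_holes),
            class = "segmentation_config")
}

#' Segment the dyed film in one frame
#'
#' @param frame Numeric h x w x 3 RGB array with values in 0..1.
#' @param config A [segmentation_config()].
#' @return Logical mask of film pixels, same h x w as the frame.
#' @export
segment_frame <- function(frame, config = segmentation_config()) {
  if (is.null(dim(frame)) || length(dim(frame)) != 3 ||
      dim(frame)[3] < 3 || any(dim(frame)[1:2] == 0))
    stop("frame must be a non-empty h x w x 3 RGB array")
  if (config$mode == "chroma") {
    pink <- frame[, , 1] - frame[, , 2]
    thr <- config$threshold
    if (isTRUE(config$auto_threshold)) {
      scaled <- (pink + 1) / 2
      thr <- 2 * EBImage::otsu(scaled, range = c(0, 1)) - 1
    }
    mask <- pink > thr
  } else {
    # gradient magnitude of luminance, auto-thresholded, closed and filled
    lum <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] +
      0.114 * frame[, , 3]
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
    gx <- EBImage::filter2(lum, kx)
    gy <- EBImage::filter2(lum, t(kx))
    g <- sqrt(gx^2 + gy^2)
    thr <- EBImage::otsu(pmin(g, 1), range = c(0, 1))
    edges <- g > thr
    brush <- EBImage::makeBrush(5, shape = "box")
    closed <- EBImage::erode(EBImage::dilate(edges, brush), brush)
    mask <- EBImage::imageData(EBImage::fillHull(closed)) > 0.5
  }
  if (config$opening_px > 1)
    mask <- morph_open(mask, as.integer(config$opening_px))
  if (isTRUE(config$fill_holes))
    mask <- fill_holes(mask)
  dim(mask) <- dim(frame)[1:2]
  mask
}

#' Label 8-connected foreground components
#'
#' Thin wrapper over the compiled flood-fill labeller; labels are assigned
#' in column-major scan order.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background) with an
#'   `n_labels` attribute.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  cc_label8(matrix(as.logical(mask), nrow(mask), ncol(mask)))
}
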