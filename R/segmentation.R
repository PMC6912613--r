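#' Local brightness-variability map
#'
#' Phase-contrast images of cells show strong local intensity fluctuations,
#' while cell-free substrate is optically quiet. Each output pixel is the
#' (population) variance of the intensities in its `(2r+1) x (2r+1)`
#' neighborhood, with reflected padding at the frame edge.
#'
#' @param frame a [calibrated_frame()].
#' @param window_radius neighborhood radius `r` in pixels (>= 1); default 3
#'   (a 7x7 window) covers the typical phase-contrast texture scale at 10x.
#' @return numeric matrix of local variances (non-negative), same shape as
#'   the frame.
#' @export
local_variability_map <- function(frame, window_radius = 3L) {
  stop_if_not(inherits(frame, "CalibratedFrame"), "frame must be a CalibratedFrame")
  r <- as.integer(window_radius)
  stop_if_not(r >= 1, "window_radius must be >= 1")
  m <- frame$pixels
  stop_if_not(2L * r + 1L <= min(dim(m)), "window larger than image")
  w2 <- (2 * r + 1)^2
  mu <- box_sum(m, r, "reflect") / w2
  m2 <- box_sum(m^2, r, "reflect") / w2
  pmax(m2 - mu^2, 0)
}

#' Segment cell-covered area by local brightness variability
#'
#' Thresholds the [local_variability_map()], then applies a morphological
#' closing (radius `close_radius`) and hole filling to suppress speckle, and
#' finally a small compensation erosion: at the default threshold the
#' variance kernel places the detected boundary roughly half a window radius
#' outside the true cell edge, so the mask is eroded by `edge_erode` pixels
#' to re-center it.
#'
#' With `threshold = "auto"` the threshold is chosen by Otsu's method on the
#' log-variance map, which makes the segmentation invariant to affine
#' intensity rescaling. Otsu assumes both phases are present; if the two
#' classes it finds differ by less than `min_contrast_ratio` in variance the
#' map is effectively unimodal and the frame is treated as uniformly
#' textured, i.e. fully covered, with a warning (an absolute cell/background
#' decision is impossible within a contrast-free frame — supply a fixed
#' `threshold` for that). A constant frame has no variability at all and
#' yields an empty mask with a warning.
#'
#' @param frame a [calibrated_frame()].
#' @param window_radius variance window radius in pixels.
#' @param threshold variance threshold, or `"auto"` for Otsu on the
#'   log-variance map.
#' @param min_contrast_ratio minimum variance ratio between the Otsu classes
#'   for the automatic threshold to count as bimodal (default 3).
#' @param close_radius radius of the morphological closing (0 disables).
#' @param fill_holes fill enclosed background holes in the mask.
#' @param edge_erode radius of the boundary-compensation erosion (0 disables).
#' @return a [binary_mask()].
#' @export
segment_cells <- function(frame, window_radius = 3L, threshold = "auto",
                          close_radius = 1L, fill_holes = TRUE,
                          edge_erode = 1L, min_contrast_ratio = 3) {
  v <- local_variability_map(frame, window_radius)
  if (identical(threshold, "auto")) {
    if (diff(range(v)) == 0) {
      warning("constant variability map: no bimodality, returning empty mask")
      return(binary_mask(matrix(0L, nrow(v), ncol(v)), frame$pixel_size))
    }
    lv <- log(v + 1e-12 * max(v))
    th <- otsu_threshold(lv)
    sep <- mean(lv[lv > th]) - mean(lv[lv <= th])
    if (!is.finite(sep) || sep < log(min_contrast_ratio)) {
      warning("variability map effectively unimodal: treating frame as uniformly covered")
      return(binary_mask(matrix(1L, nrow(v), ncol(v)), frame$pixel_size))
    }
    mask <- (lv > th) * 1L
  } else {
    stop_if_not(is.numeric(threshold) && length(threshold) == 1,
                "threshold must be a single variance value or \"auto\"")
    mask <- (v > threshold) * 1L
  }
  if (close_radius > 0) mask <- bin_close(mask, as.integer(close_radius))
  if (fill_holes) mask <- fill_mask_holes(mask)
  if (edge_erode > 0) mask <- bin_erode(mask, as.integer(edge_erode))
  binary_mask(mask, frame$pixel_size)
}

fill_mask_holes <- function(m) {
  f <- EBImage::imageData(EBImage::fillHull(m))
  storage.mode(f) <- "integer"
  f
}

#' Confluency time series
#'
#' Per-frame cell-covered fraction (mask area / frame area) of a time-lapse
#' sequence.
#'
#' @param seq a [time_lapse()].
#' @param ... parameters forwarded to [segment_cells()].
#' @return data frame of class `ConfluencySeries` with columns `time`
#'   (hours) and `covered_fraction` (in `[0, 1]`), one row per frame.
#' @export
confluency_series <- function(seq, ...) {
  stop_if_not(inherits(seq, "TimeLapse"), "seq must be a TimeLapse")
  fr <- vapply(seq$frames, function(f) coverage_fraction(segment_cells(f, ...)),
               numeric(1))
  out <- data.frame(time = frame_times(seq$frames), covered_fraction = fr)
  class(out) <- c("ConfluencySeries", class(out))
  out
}
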