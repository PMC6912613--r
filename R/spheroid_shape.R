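#' Normalized perimeter (shape compactness)
#'
#' Ratio of a shape's perimeter to the perimeter of the circle with the same
#' area, `P / (2 * sqrt(pi * A))`. Equals 1 for a disk, `2/sqrt(pi)` for a
#' square, and grows with boundary roughness; loose, irregular aggregates
#' score high.
#'
#' @param area area in µm² (> 0).
#' @param perimeter perimeter in µm (> 0).
#' @return dimensionless ratio >= ~1.
#' @export
normalized_perimeter <- function(area, perimeter) {
  stop_if_not(all(area > 0) && all(perimeter > 0),
              "area and perimeter must be > 0")
  perimeter / (2 * sqrt(pi * area))
}

# Sub-pixel perimeter of a binary mask: Gaussian-smooth the indicator and
# measure the 0.5 iso-contour with marching squares (grDevices::contourLines).
# Pixel-edge counting overestimates perimeters by up to 4/pi; the smoothed
# iso-contour is accurate to a fraction of a percent for objects >= ~100 px
# across. The longest contour is the outer boundary.
mask_perimeter_px <- function(m, smooth_sigma = 1.5) {
  # zero-pad so objects touching the frame edge still yield closed contours
  p <- matrix(0, nrow(m) + 10L, ncol(m) + 10L)
  p[6:(5L + nrow(m)), 6:(5L + ncol(m))] <- m
  ms <- if (smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(p, sigma = smooth_sigma))
  else p
  cl <- contourLines(seq_len(nrow(ms)), seq_len(ncol(ms)), ms, levels = 0.5)
  stop_if_not(length(cl) > 0, "no contour found (empty or full mask)")
  plen <- function(cc) {
    x <- cc$x; y <- cc$y
    sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  }
  max(vapply(cl, plen, numeric(1)))
}

#' Shape metrics of a spheroid mask
#'
#' Area from the pixel count, perimeter from the sub-pixel iso-contour of
#' the smoothed mask, and their [normalized_perimeter()].
#'
#' @param mask a [binary_mask()] containing a single (hole-free) aggregate.
#' @param smooth_sigma Gaussian smoothing (px) applied to the mask before
#'   contouring; 0 disables. Default 1.5 suppresses rasterization ripple.
#' @return list of class `SpheroidOutline`: `mask`, `area` (µm²),
#'   `perimeter` (µm), `normalized_perimeter`.
#' @export
spheroid_metrics <- function(mask, smooth_sigma = 1.5) {
  stop_if_not(inherits(mask, "BinaryMask"), "mask must be a BinaryMask")
  px <- sum(mask$pixels)
  stop_if_not(px > 0, "empty mask")
  ps <- mask$pixel_size
  area <- px * ps^2
  per <- mask_perimeter_px(mask$pixels, smooth_sigma) * ps
  structure(list(mask = mask, area = area, perimeter = per,
                 normalized_perimeter = normalized_perimeter(area, per)),
            class = "SpheroidOutline")
}

#' @export
print.SpheroidOutline <- function(x, ...) {
  cat(sprintf("SpheroidOutline: area %.4g um^2, perimeter %.4g um, P/Pcircle = %.4f\n",
              x$area, x$perimeter, x$normalized_perimeter))
  invisible(x)
}

#' Extract the dominant spheroid from a micrograph
#'
#' Segments the frame ([segment_cells()]), keeps the largest connected
#' component (8-connectivity), fills its holes, and measures it with
#' [spheroid_metrics()]. Loose satellite clusters disconnected from the
#' aggregate are excluded; connected protrusions count toward the perimeter.
#'
#' @param frame a [calibrated_frame()] with one dominant aggregate.
#' @param smooth_sigma see [spheroid_metrics()].
#' @param ... segmentation parameters forwarded to [segment_cells()].
#' @return a `SpheroidOutline`.
#' @export
extract_spheroid <- function(frame, smooth_sigma = 1.5, ...) {
  mask <- segment_cells(frame, ...)
  stop_if_not(sum(mask$pixels) > 0, "empty segmentation: no spheroid found")
  lab <- label_components(mask$pixels, 8L)
  sizes <- tabulate(lab[lab > 0L], max(lab))
  big <- fill_mask_holes((lab == which.max(sizes)) * 1L)
  spheroid_metrics(binary_mask(big, frame$pixel_size), smooth_sigma)
}

#' Spheroid compactness time series
#'
#' Per-frame normalized perimeter during aggregation. Accepts a
#' [time_lapse()] (frames are segmented) or a list of [binary_mask()]s
#' paired with times.
#'
#' @param seq a `TimeLapse`, or a list of `BinaryMask`s.
#' @param times frame times in hours (required for a mask list).
#' @param smooth_sigma see [spheroid_metrics()].
#' @param ... forwarded to [extract_spheroid()].
#' @return data frame with columns `time`, `area`, `perimeter`,
#'   `normalized_perimeter`.
#' @export
compactness_series <- function(seq, times = NULL, smooth_sigma = 1.5, ...) {
  if (inherits(seq, "TimeLapse")) {
    outl <- lapply(seq$frames, extract_spheroid, smooth_sigma = smooth_sigma, ...)
    times <- frame_times(seq$frames)
  } else {
    stop_if_not(is.list(seq) && all(vapply(seq, inherits, TRUE, "BinaryMask")),
                "seq must be a TimeLapse or a list of BinaryMask objects")
    stop_if_not(!is.null(times) && length(times) == length(seq),
                "times must accompany a mask list")
    outl <- lapply(seq, spheroid_metrics, smooth_sigma = smooth_sigma)
  }
  data.frame(time = times,
             area = vapply(outl, `[[`, numeric(1), "area"),
             perimeter = vapply(outl, `[[`, numeric(1), "perimeter"),
             normalized_perimeter = vapply(outl, `[[`, numeric(1),
                                           "normalized_perimeter"))
}

#' Average per-frame series across fields
#'
#' Aligns `(time, value)` series from several fields or spheroids on their
#' common time points and reports mean, SEM and n per time point.
#'
#' @param series_list list of data frames with a `time` column and one value
#'   column named by `value`.
#' @param value name of the value column.
#' @return data frame with `time`, `mean`, `sem`, `n`.
#' @export
summarize_fields <- function(series_list, value) {
  stop_if_not(is.list(series_list) && length(series_list) >= 1,
              "need >= 1 series")
  times <- sort(unique(round(unlist(lapply(series_list, `[[`, "time")), 9)))
  vm <- sapply(times, function(tt) {
    v <- unlist(lapply(series_list, function(s)
      s[[value]][round(s$time, 9) == tt]))
    mean_sem(v[is.finite(v)])
  })
  data.frame(time = times, mean = vm["mean", ], sem = vm["sem", ],
             n = vm["n", ])
}
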