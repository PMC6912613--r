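#' Calibrated image frame
#'
#' The elementary unit all spatial metrics are computed on: a single-channel
#' intensity image together with its spatial calibration (micrometres per
#' pixel) and acquisition time. Pixel coordinates are 1-based `(row, col)`
#' with the origin at the top-left; the physical position of pixel
#' `(i, j)` is `((i - 1) * pixel_size, (j - 1) * pixel_size)` µm.
#'
#' @param pixels numeric matrix of intensities (arbitrary units).
#' @param pixel_size spatial calibration, µm per pixel (> 0). Calibration is
#'   always user-supplied; it is never inferred from image files.
#' @param time acquisition time in hours post-seeding (>= 0).
#' @param channel free-text channel label.
#' @return an object of class `CalibratedFrame`.
#' @examples
#' f <- calibrated_frame(matrix(rnorm(64 * 64), 64), pixel_size = 1.3)
#' f$pixel_size
#' @export
calibrated_frame <- function(pixels, pixel_size, time = 0, channel = "") {
  pixels <- as.matrix(pixels)
  stop_if_not(is.numeric(pixels) && length(pixels) > 0,
              "pixels must be a non-empty numeric matrix")
  stop_if_not(is.numeric(pixel_size) && length(pixel_size) == 1 &&
                pixel_size > 0, "pixel_size must be a single value > 0")
  stop_if_not(is.numeric(time) && length(time) == 1 && time >= 0,
              "time must be a single value >= 0 (hours)")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 time = time, channel = as.character(channel)),
            class = "CalibratedFrame")
}

#' @export
print.CalibratedFrame <- function(x, ...) {
  cat(sprintf("CalibratedFrame %d x %d px, %.4g um/px, t = %.4g h%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$time,
              if (nzchar(x$channel)) paste0(" [", x$channel, "]") else ""))
  invisible(x)
}

#' Time-lapse sequence of calibrated frames
#'
#' @param frames list of [calibrated_frame()] objects sharing shape and
#'   calibration, with strictly increasing times.
#' @param interval_min nominal frame interval in minutes (> 0).
#' @return an object of class `TimeLapse`.
#' @export
time_lapse <- function(frames, interval_min) {
  stop_if_not(is.list(frames) && length(frames) > 0, "frames must be a non-empty list")
  stop_if_not(all(vapply(frames, inherits, TRUE, "CalibratedFrame")),
              "all frames must be CalibratedFrame objects")
  stop_if_not(interval_min > 0, "interval_min must be > 0")
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  stop_if_not(all(dims == dims[, 1]), "all frames must share one shape")
  ps <- vapply(frames, `[[`, numeric(1), "pixel_size")
  stop_if_not(all(ps == ps[1]), "all frames must share one pixel_size")
  tt <- frame_times(frames)
  stop_if_not(length(tt) < 2 || all(diff(tt) > 0),
              "frame times must be strictly increasing")
  structure(list(frames = frames, interval = interval_min),
            class = "TimeLapse")
}

frame_times <- function(frames) vapply(frames, `[[`, numeric(1), "time")

#' @export
print.TimeLapse <- function(x, ...) {
  tt <- frame_times(x$frames)
  cat(sprintf("TimeLapse: %d frames, %.4g min interval, t in [%.3g, %.3g] h\n",
              length(x$frames), x$interval, min(tt), max(tt)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' Carrier for all segmentations: pixel values exactly 0 (background) or 1
#' (cell-covered), with the same calibration contract as its source frame.
#'
#' @param pixels matrix with values in \{0, 1\} (logical accepted).
#' @param pixel_size µm per pixel (> 0).
#' @return an object of class `BinaryMask`.
#' @export
binary_mask <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) pixels[] <- as.integer(pixels)
  stop_if_not(all(pixels %in% c(0, 1)), "mask values must be exactly 0 or 1")
  stop_if_not(pixel_size > 0, "pixel_size must be > 0")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask %d x %d px, %.4g um/px, covered %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              mean(x$pixels)))
  invisible(x)
}

#' Fraction of the field covered by a mask
#'
#' @param mask a [binary_mask()].
#' @return covered fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(mask) {
  stop_if_not(inherits(mask, "BinaryMask"), "mask must be a BinaryMask")
  mean(mask$pixels)
}

read_frame_pixels <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    png = png::readPNG(path),
    stop("unsupported image format: ", path, call. = FALSE))
  if (!is.list(img)) img <- list(img)
  lapply(img, function(a) {
    if (length(dim(a)) == 3L) {
      if (dim(a)[3] == 1L) a <- a[, , 1] else
        stop("not a single-channel image: ", path, call. = FALSE)
    }
    as.matrix(a)
  })
}

#' Load an image sequence as a calibrated time lapse
#'
#' Reads single-channel TIFF (single- or multi-page) and PNG frames. Frames
#' are ordered by input order (a multi-page TIFF contributes its pages in
#' file order) and times are assigned as `index * interval / 60` hours,
#' starting at 0.
#'
#' @param paths ordered character vector of image files.
#' @param pixel_size µm per pixel.
#' @param interval_min minutes between consecutive frames.
#' @return a [time_lapse()].
#' @export
load_sequence <- function(paths, pixel_size, interval_min) {
  stop_if_not(length(paths) > 0, "empty path list")
  mats <- list()
  for (p in paths) {
    stop_if_not(file.exists(p), paste0("unreadable file: ", p))
    pages <- read_frame_pixels(p)
    if (length(mats) > 0 &&
        !all(vapply(pages, function(m) identical(dim(m), dim(mats[[1]])), TRUE)))
      stop("frame shape mismatch in file: ", p, call. = FALSE)
    mats <- c(mats, pages)
  }
  stop_if_not(length(mats) > 0, "no frames read")
  frames <- lapply(seq_along(mats), function(i)
    calibrated_frame(mats[[i]], pixel_size,
                     time = (i - 1) * interval_min / 60))
  time_lapse(frames, interval_min)
}

#' Write a frame or mask as a PNG image
#'
#' Intensities are rescaled to `[0, 1]`; integer images in `[0, 255]` are
#' written losslessly at 8 bits so that a write/read round trip preserves
#' pixel values exactly.
#'
#' @param x a [calibrated_frame()] or [binary_mask()].
#' @param path output file.
#' @export
write_frame_png <- function(x, path) {
  m <- x$pixels
  if (all(m == round(m)) && min(m) >= 0 && max(m) <= 255) {
    png::writePNG(m / 255, path)
  } else {
    rng <- range(m)
    png::writePNG(if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0, path)
  }
  invisible(path)
}

#' Write tabular results to CSV
#'
#' @param records data frame (or list of equal-length columns) of results.
#' @param path output file.
#' @return the path, invisibly. A round-trip read with [read_table_csv()]
#'   returns identical values within text float precision.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    stop_if_not(is.list(records) && length(records) > 0,
                "records must be a non-empty data frame or list of columns")
    len <- vapply(records, length, integer(1))
    stop_if_not(all(len == len[1]), "columns must have equal length")
    records <- as.data.frame(records)
  }
  stop_if_not(nrow(records) > 0, "records must be non-empty")
  ok <- tryCatch({ write.csv(records, path, row.names = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, call. = FALSE)
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#' @param path CSV file.
#' @return data frame.
#' @export
read_table_csv <- function(path) {
  stop_if_not(file.exists(path), paste0("no such file: ", path))
  read.csv(path, stringsAsFactors = FALSE)
}
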