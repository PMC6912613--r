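#' PIV displacement field between two consecutive frames
#'
#' Classical window-based particle image velocimetry: the frame is tiled
#' into interrogation windows; each window of the first frame is matched
#' against the second frame by normalized cross-correlation over integer
#' shifts within `search_margin`, followed by one-dimensional parabolic
#' sub-pixel refinement of the correlation peak along each axis. A window is
#' flagged invalid when its correlation peak is below `peak_min` (no real
#' match anywhere: on fully decorrelated noise the best of ~400 candidate
#' shifts only reaches a few hundredths) or is not at least
#' `peak_ratio_min` times higher than the second-highest peak outside the
#' 3x3 neighborhood of the first (no unambiguous match).
#'
#' Identical frames produce a correlation of exactly 1 at zero shift; in
#' that case refinement is skipped and the displacement is exactly zero.
#'
#' @param frameA,frameB [calibrated_frame()]s of identical shape and
#'   calibration.
#' @param window interrogation-window side in pixels (>= 16; default 32).
#' @param overlap overlap between adjacent windows in pixels (default 16).
#' @param search_margin maximum shift searched, pixels (default 10).
#' @param peak_ratio_min validity threshold on first/second peak (default 1.1).
#' @param peak_min minimum correlation of the peak itself (default 0.2).
#' @return data frame of class `VelocityField` with columns `row`, `col`
#'   (window centers, pixels), `d_row`, `d_col` (displacement in pixels per
#'   frame interval), `peak_ratio` and `valid`. Attributes: `pixel_size`
#'   (µm/px) and `dt_h` (frame-pair time difference in hours, 0 when the
#'   frames carry no distinct times).
#' @export
piv_pair <- function(frameA, frameB, window = 32L, overlap = 16L,
                     search_margin = 10L, peak_ratio_min = 1.1,
                     peak_min = 0.2) {
  stop_if_not(inherits(frameA, "CalibratedFrame") &&
                inherits(frameB, "CalibratedFrame"),
              "frames must be CalibratedFrame objects")
  stop_if_not(identical(dim(frameA$pixels), dim(frameB$pixels)),
              "frames differ in shape")
  stop_if_not(frameA$pixel_size == frameB$pixel_size,
              "frames differ in calibration")
  w <- as.integer(window); ov <- as.integer(overlap)
  m <- as.integer(search_margin)
  stop_if_not(w >= 16L, "window must be >= 16 px")
  stop_if_not(ov >= 0L && ov < w, "overlap must be in [0, window)")
  stop_if_not(m >= 1L, "search_margin must be >= 1 px")
  A <- frameA$pixels; B <- frameB$pixels
  nr <- nrow(A); nc <- ncol(A)
  # only windows with the full search margin on all sides: a clipped search
  # range cannot contain the true shift and silently biases the field
  stop_if_not(nr >= w + 2L * m && nc >= w + 2L * m,
              "image smaller than window + 2 * search_margin")
  step <- w - ov
  orig_r <- seq(1L + m, nr - w + 1L - m, by = step)
  orig_c <- seq(1L + m, nc - w + 1L - m, by = step)
  res <- vector("list", length(orig_r) * length(orig_c))
  k <- 0L
  for (i0 in orig_r) for (j0 in orig_c) {
    k <- k + 1L
    res[[k]] <- piv_window(A, B, i0, j0, w, m, peak_ratio_min, peak_min)
  }
  out <- do.call(rbind, res)
  attr(out, "pixel_size") <- frameA$pixel_size
  attr(out, "dt_h") <- frameB$time - frameA$time
  class(out) <- c("VelocityField", class(out))
  out
}

piv_window <- function(A, B, i0, j0, w, m, peak_ratio_min, peak_min) {
  mr_lo <- mr_hi <- mc_lo <- mc_hi <- m
  R <- B[(i0 - mr_lo):(i0 + w - 1L + mr_hi),
         (j0 - mc_lo):(j0 + w - 1L + mc_hi), drop = FALSE]
  nrR <- nrow(R)
  dr <- -mr_lo:mr_hi; dc <- -mc_lo:mc_hi
  base <- as.vector(outer(seq_len(w), (seq_len(w) - 1L) * nrR, `+`))
  offs <- as.vector(outer(dr + mr_lo, (dc + mc_lo) * nrR, `+`))
  Bmat <- matrix(R[outer(base, offs, `+`)], nrow = w * w)
  a <- as.vector(A[i0:(i0 + w - 1L), j0:(j0 + w - 1L)])
  ncc <- suppressWarnings(as.vector(cor(a, Bmat)))
  ncc[!is.finite(ncc)] <- -Inf
  cc <- matrix(ncc, length(dr), length(dc))
  pk <- arrayInd(which.max(cc), dim(cc))
  peak <- cc[pk]
  # second peak outside the 3x3 neighborhood of the first
  excl <- cc
  excl[max(1, pk[1] - 1):min(nrow(cc), pk[1] + 1),
       max(1, pk[2] - 1):min(ncol(cc), pk[2] + 1)] <- -Inf
  second <- suppressWarnings(max(excl))
  ratio <- if (!is.finite(second) || second <= 0) Inf else peak / second
  valid <- is.finite(peak) && peak >= peak_min && ratio >= peak_ratio_min
  d_row <- dr[pk[1]]; d_col <- dc[pk[2]]
  if (valid && peak < 1 - 1e-10) {
    d_row <- d_row + parabolic_offset(cc, pk, axis = 1L)
    d_col <- d_col + parabolic_offset(cc, pk, axis = 2L)
  }
  data.frame(row = i0 + (w - 1) / 2, col = j0 + (w - 1) / 2,
             d_row = d_row, d_col = d_col,
             peak_ratio = if (is.finite(ratio)) ratio else NA_real_,
             valid = valid)
}

parabolic_offset <- function(cc, pk, axis) {
  i <- pk[1]; j <- pk[2]
  n <- if (axis == 1L) nrow(cc) else ncol(cc)
  at <- if (axis == 1L) i else j
  if (at <= 1L || at >= n) return(0)
  cm <- if (axis == 1L) cc[i - 1L, j] else cc[i, j - 1L]
  cp <- if (axis == 1L) cc[i + 1L, j] else cc[i, j + 1L]
  c0 <- cc[i, j]
  den <- cm - 2 * c0 + cp
  if (!is.finite(cm) || !is.finite(cp) || den >= 0) return(0)
  max(-1, min(1, 0.5 * (cm - cp) / den))
}

#' Mean motility speed of one PIV field
#'
#' Mean displacement magnitude over valid windows, converted to µm/h with
#' the frame calibration and the frame-pair interval. When a mask is given,
#' only windows whose center lies on a cell-covered pixel contribute, so
#' decorrelated background does not dilute the estimate.
#'
#' @param field a `VelocityField` from [piv_pair()].
#' @param mask optional [binary_mask()] restricting the averaged windows.
#' @param interval_min frame interval in minutes; only needed when the field
#'   carries no time difference (`dt_h` attribute 0).
#' @return speed in µm/h; `NA` with a warning when no valid window remains.
#' @export
frame_speed <- function(field, mask = NULL, interval_min = NULL) {
  stop_if_not(inherits(field, "VelocityField"), "field must be a VelocityField")
  dt_h <- attr(field, "dt_h")
  if (!is.numeric(dt_h) || dt_h <= 0) {
    stop_if_not(!is.null(interval_min) && interval_min > 0,
                "frame pair carries no time difference; supply interval_min")
    dt_h <- interval_min / 60
  }
  keep <- field$valid
  if (!is.null(mask)) {
    stop_if_not(inherits(mask, "BinaryMask"), "mask must be a BinaryMask")
    ij <- cbind(pmin(pmax(round(field$row), 1), nrow(mask$pixels)),
                pmin(pmax(round(field$col), 1), ncol(mask$pixels)))
    keep <- keep & mask$pixels[ij] == 1L
  }
  if (!any(keep)) {
    warning("no valid PIV window; speed undefined")
    return(NA_real_)
  }
  ps <- attr(field, "pixel_size")
  mean(sqrt(field$d_row[keep]^2 + field$d_col[keep]^2)) * ps / dt_h
}

#' Condition-level motility speed time series
#'
#' Computes [piv_pair()] speeds for every consecutive frame pair of every
#' field (time lapse) of a condition and averages them per time point across
#' fields. Frames at or beyond `t_max` hours are excluded before pairing
#' (half-open window `[0, t_max)`), restricting the analysis to the
#' pre-confluent growth phase.
#'
#' @param sequences list of [time_lapse()] objects, one per microscopic
#'   field (>= 1).
#' @param t_max analysis horizon in hours (default 100).
#' @param use_mask segment each pair's first frame and average only over
#'   cell-covered windows (default TRUE).
#' @param window,overlap,search_margin PIV parameters, see [piv_pair()].
#' @param seg_params list of extra arguments to [segment_cells()].
#' @return data frame of class `SpeedSeries` with columns `time` (h, of the
#'   first frame of each pair), `mean_speed` (µm/h), `sem` and `n_fields`;
#'   attribute `fields` holds the underlying per-field speed matrix
#'   (fields x timepoints) for significance testing.
#' @export
speed_timeseries <- function(sequences, t_max = 100, use_mask = TRUE,
                             window = 32L, overlap = 16L, search_margin = 10L,
                             seg_params = list()) {
  stop_if_not(is.list(sequences) && length(sequences) >= 1 &&
                all(vapply(sequences, inherits, TRUE, "TimeLapse")),
              "sequences must be a non-empty list of TimeLapse objects")
  per_field <- lapply(sequences, function(sq) {
    tt <- frame_times(sq$frames)
    keep <- which(tt < t_max)
    if (length(keep) < 2) return(data.frame(time = numeric(), speed = numeric()))
    sp <- vapply(keep[-length(keep)], function(i) {
      fld <- piv_pair(sq$frames[[i]], sq$frames[[i + 1L]], window = window,
                      overlap = overlap, search_margin = search_margin)
      msk <- if (use_mask)
        do.call(segment_cells, c(list(sq$frames[[i]]), seg_params)) else NULL
      frame_speed(fld, mask = msk, interval_min = sq$interval)
    }, numeric(1))
    data.frame(time = tt[keep[-length(keep)]], speed = sp)
  })
  times <- sort(unique(round(unlist(lapply(per_field, `[[`, "time")), 9)))
  stop_if_not(length(times) > 0, "no frame pairs before t_max in any field")
  fm <- matrix(NA_real_, length(per_field), length(times))
  for (f in seq_along(per_field)) {
    idx <- match(round(per_field[[f]]$time, 9), times)
    fm[f, idx] <- per_field[[f]]$speed
  }
  stats_t <- apply(fm, 2, function(x) mean_sem(x[is.finite(x)]))
  out <- data.frame(time = times, mean_speed = stats_t["mean", ],
                    sem = stats_t["sem", ], n_fields = stats_t["n", ])
  rownames(out) <- NULL
  attr(out, "fields") <- fm
  class(out) <- c("SpeedSeries", class(out))
  out
}
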