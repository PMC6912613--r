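#' Single-cell trajectory
#'
#' @param t_h sample times in hours, strictly increasing (>= 2 samples).
#' @param x_um,y_um positions in µm.
#' @param cell_id identifier.
#' @return data frame of class `Trajectory` with columns `t_h`, `x_um`,
#'   `y_um` and attribute `cell_id`.
#' @export
trajectory <- function(t_h, x_um, y_um, cell_id = "cell") {
  stop_if_not(length(t_h) >= 2, "a trajectory needs >= 2 samples")
  stop_if_not(length(x_um) == length(t_h) && length(y_um) == length(t_h),
              "t_h, x_um, y_um must have equal length")
  stop_if_not(all(diff(t_h) > 0), "sample times must be strictly increasing")
  out <- data.frame(t_h = t_h, x_um = x_um, y_um = y_um)
  attr(out, "cell_id") <- as.character(cell_id)
  class(out) <- c("Trajectory", class(out))
  out
}

#' Read manually tracked trajectories from CSV
#'
#' Expects columns `cell_id`, `t_h`, `x_um`, `y_um` (one row per sample).
#'
#' @param path CSV file.
#' @return list of [trajectory()] objects, one per cell.
#' @export
read_tracks <- function(path) {
  d <- read_table_csv(path)
  need <- c("cell_id", "t_h", "x_um", "y_um")
  stop_if_not(all(need %in% names(d)),
              paste("track file must have columns:", paste(need, collapse = ", ")))
  lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$t_h), ]
    trajectory(g$t_h, g$x_um, g$y_um, cell_id = g$cell_id[1])
  })
}

#' Net displacements over sliding time windows
#'
#' For each window start (stepped by `stride` samples), the straight-line
#' distance between the position at the start and the sample nearest to
#' `start + duration`, accepted only if that sample lies within half a
#' sampling interval of the target time. Windows extending past the track
#' end are skipped.
#'
#' @param track a [trajectory()].
#' @param duration window duration in hours (>= the sampling interval).
#' @param stride step between window starts, in samples (>= 1).
#' @return numeric vector of displacements (µm), possibly empty (with a
#'   warning when the duration exceeds the track span).
#' @export
net_displacements <- function(track, duration, stride = 1L) {
  stop_if_not(inherits(track, "Trajectory"), "track must be a Trajectory")
  stop_if_not(stride >= 1, "stride must be >= 1")
  t <- track$t_h
  dt <- median(diff(t))
  stop_if_not(duration >= dt, "duration shorter than the sampling interval")
  if (duration > t[length(t)] - t[1]) {
    warning("duration exceeds track span; no windows")
    return(numeric(0))
  }
  starts <- seq(1L, length(t), by = as.integer(stride))
  target <- t[starts] + duration
  lo <- findInterval(target, t)
  hi <- pmin(lo + 1L, length(t))
  lo <- pmax(lo, 1L)
  nearest <- ifelse(abs(t[lo] - target) <= abs(t[hi] - target), lo, hi)
  ok <- abs(t[nearest] - target) <= dt / 2 & nearest > starts
  s <- starts[ok]; e <- nearest[ok]
  sqrt((track$x_um[e] - track$x_um[s])^2 + (track$y_um[e] - track$y_um[s])^2)
}

#' Mean net-displacement curve over a set of trajectories
#'
#' Pools windows of each duration across all cells and reports their mean
#' and SEM. With overlapping windows (`stride = 1`, the default) consecutive
#' windows are strongly correlated, so the SEM denominator uses the
#' effective number of non-overlapping windows rather than the pooled window
#' count. `per_cell = TRUE` instead averages within each cell first and
#' takes mean and SEM over cells.
#'
#' @param tracks list of [trajectory()] objects (>= 1).
#' @param durations window durations in hours.
#' @param stride window step in samples.
#' @param per_cell average per cell before pooling (default FALSE).
#' @return data frame of class `DisplacementCurve` with columns
#'   `window_duration` (h), `mean_net_displacement` (µm), `sem` (µm) and
#'   `n_windows`.
#' @export
displacement_curve <- function(tracks, durations, stride = 1L,
                               per_cell = FALSE) {
  stop_if_not(is.list(tracks) && length(tracks) >= 1 &&
                all(vapply(tracks, inherits, TRUE, "Trajectory")),
              "tracks must be a non-empty list of Trajectory objects")
  rows <- lapply(durations, function(dur) {
    per <- lapply(tracks, function(tr)
      suppressWarnings(net_displacements(tr, dur, stride)))
    pooled <- unlist(per)
    n_win <- length(pooled)
    if (n_win == 0)
      return(data.frame(window_duration = dur,
                        mean_net_displacement = NA_real_, sem = NA_real_,
                        n_windows = 0L))
    if (per_cell) {
      cm <- vapply(per[vapply(per, length, integer(1)) > 0], mean, numeric(1))
      ms <- mean_sem(cm)
      data.frame(window_duration = dur, mean_net_displacement = ms["mean"],
                 sem = ms["sem"], n_windows = n_win)
    } else {
      n_eff <- sum(vapply(tracks, function(tr)
        max(floor((tr$t_h[nrow(tr)] - tr$t_h[1]) / dur), 0), numeric(1)))
      n_eff <- max(n_eff, 1)
      data.frame(window_duration = dur, mean_net_displacement = mean(pooled),
                 sem = if (n_win > 1) sd(pooled) / sqrt(n_eff) else 0,
                 n_windows = n_win)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("DisplacementCurve", class(out))
  out
}
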