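# Collagen-invasion quantification: area fraction of cell clusters detached
# from the central spheroid aggregate.

#' Split a mask into the central aggregate and solitary clusters
#'
#' The central aggregate is the largest 8-connected component (ties broken
#' deterministically toward the component first reached in raster order,
#' i.e. the lowest label, with a message). Solitary clusters are all other
#' components of at least `min_area`; smaller components are discarded as
#' debris but accounted for in the conservation bookkeeping.
#'
#' @param mask a non-empty [binary_mask()].
#' @param min_area minimum solitary-cluster area in µm² (default 50, shared
#'   with the cluster-analysis defaults).
#' @return list with `central` and `solitary` ([binary_mask()]s, disjoint
#'   subsets of `mask`), `central_area`, `solitary_area`, `discarded_area`
#'   (µm²) and `solitary_fraction` = solitary / (central + solitary).
#' @export
split_central_solitary <- function(mask, min_area = 50) {
  stop_if_not(inherits(mask, "BinaryMask"), "mask must be a BinaryMask")
  stop_if_not(sum(mask$pixels) > 0, "empty mask: no aggregate present")
  ps <- mask$pixel_size
  lab <- label_components(mask$pixels, 8L)
  sizes <- tabulate(lab[lab > 0L], max(lab))
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1)
    message("tie for largest component; using the first in raster order")
  central_id <- biggest[1]
  central <- (lab == central_id) * 1L
  others <- which(sizes * ps^2 >= min_area)
  others <- setdiff(others, central_id)
  solitary <- (matrix(lab %in% others, nrow(lab), ncol(lab))) * 1L
  discarded <- (sum(sizes) - sizes[central_id] - sum(sizes[others])) * ps^2
  ca <- sizes[central_id] * ps^2
  sa <- sum(sizes[others]) * ps^2
  list(central = binary_mask(central, ps),
       solitary = binary_mask(solitary, ps),
       central_area = ca, solitary_area = sa, discarded_area = discarded,
       solitary_fraction = sa / (ca + sa))
}

#' Solitary-cluster invasion time series
#'
#' Per-frame fraction of the cell-covered area contributed by clusters
#' detached from the central aggregate. Accepts a [time_lapse()] (each
#' frame is segmented) or a list of [binary_mask()]s with `times`. Frames
#' whose segmentation is empty (e.g. the aggregate has left the field) are
#' flagged as `NA` with a warning rather than silently scored.
#'
#' @param seq a `TimeLapse` or a list of `BinaryMask`s.
#' @param times frame times in hours (required for a mask list).
#' @param min_area see [split_central_solitary()].
#' @param ... segmentation parameters forwarded to [segment_cells()].
#' @return data frame of class `InvasionSeries` with columns `time`,
#'   `central_area`, `solitary_area` (µm²) and `solitary_fraction`.
#' @export
invasion_series <- function(seq, times = NULL, min_area = 50, ...) {
  if (inherits(seq, "TimeLapse")) {
    masks <- lapply(seq$frames, segment_cells, ...)
    times <- frame_times(seq$frames)
  } else {
    stop_if_not(is.list(seq) && all(vapply(seq, inherits, TRUE, "BinaryMask")),
                "seq must be a TimeLapse or a list of BinaryMask objects")
    stop_if_not(!is.null(times) && length(times) == length(seq),
                "times must accompany a mask list")
    masks <- seq
  }
  rows <- lapply(seq_along(masks), function(i) {
    if (sum(masks[[i]]$pixels) == 0) {
      warning(sprintf("frame %d: empty segmentation, no aggregate scored", i))
      return(data.frame(time = times[i], central_area = NA_real_,
                        solitary_area = NA_real_,
                        solitary_fraction = NA_real_))
    }
    s <- split_central_solitary(masks[[i]], min_area = min_area)
    data.frame(time = times[i], central_area = s$central_area,
               solitary_area = s$solitary_area,
               solitary_fraction = s$solitary_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("InvasionSeries", class(out))
  out
}
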