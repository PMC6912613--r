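# Connected-component analysis of segmentation masks: cluster tables,
# size-distribution histograms, and the small-cluster band frequency.

label_components <- function(m, connectivity = 8L) {
  stop_if_not(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  lab <- EBImage::imageData(EBImage::bwlabel(m))   # 4-connected labels
  storage.mode(lab) <- "integer"
  if (connectivity == 8L && max(lab) > 1L) {
    # merge labels that touch diagonally
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(edges) > 0) {
      g <- igraph::make_graph(edges = as.vector(t(edges)), n = max(lab),
                              directed = FALSE)
      comp <- igraph::components(g)$membership
      lab[lab > 0L] <- comp[lab[lab > 0L]]
    }
  }
  # relabel compactly in raster order of first occurrence
  u <- unique(lab[lab > 0L])
  if (length(u) > 0) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Label cell clusters in a segmentation mask
#'
#' Connected components of the mask under 4- or 8-connectivity (default 8:
#' diagonally touching cells count as one cluster). Components smaller than
#' `min_area` are discarded as debris but their total area is retained for
#' the area-conservation bookkeeping.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 4 or 8.
#' @param min_area minimum cluster area in µm² (default 50).
#' @return data frame of class `ClusterTable` with columns `label`, `area`
#'   (µm²), `centroid_x`, `centroid_y` (µm, row/col axes), and
#'   `touches_border`. Attributes: `pixel_size`, `total_mask_area`
#'   (µm², full mask) and `discarded_area` (µm² in sub-`min_area`
#'   components).
#' @export
label_clusters <- function(mask, connectivity = 8L, min_area = 50) {
  stop_if_not(inherits(mask, "BinaryMask"), "mask must be a BinaryMask")
  ps <- mask$pixel_size
  lab <- label_components(mask$pixels, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    tab <- data.frame(label = integer(), area = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      touches_border = logical())
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    ij <- arrayInd(idx, dim(lab))
    px <- tabulate(l, n)
    cx <- (vapply(split(ij[, 1], l), mean, numeric(1)) - 1) * ps
    cy <- (vapply(split(ij[, 2], l), mean, numeric(1)) - 1) * ps
    border <- ij[, 1] == 1L | ij[, 1] == nrow(lab) |
              ij[, 2] == 1L | ij[, 2] == ncol(lab)
    tb <- vapply(split(border, l), any, logical(1))
    tab <- data.frame(label = seq_len(n), area = px * ps^2,
                      centroid_x = as.numeric(cx), centroid_y = as.numeric(cy),
                      touches_border = as.logical(tb))
  }
  discarded <- sum(tab$area[tab$area < min_area])
  tab <- tab[tab$area >= min_area, , drop = FALSE]
  tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "pixel_size") <- ps
  attr(tab, "total_mask_area") <- sum(mask$pixels) * ps^2
  attr(tab, "discarded_area") <- discarded
  class(tab) <- c("ClusterTable", class(tab))
  tab
}

#' Cluster size-distribution histogram
#'
#' Bins cluster areas into half-open bins `[lo, hi)`. Clusters outside all
#' bins are reported in an overflow count; frequencies are normalized to the
#' number of in-bin clusters.
#'
#' @param table a `ClusterTable` (or anything with an `area` column in µm²).
#' @param bin_edges strictly increasing bin edges in µm².
#' @return list of class `ClusterSizeHistogram` with `bin_edges`, `counts`,
#'   `frequency`, and `overflow`.
#' @export
size_histogram <- function(table, bin_edges) {
  stop_if_not(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
              "bin_edges must be strictly increasing")
  a <- table$area
  k <- findInterval(a, bin_edges, rightmost.closed = FALSE)
  inbin <- k >= 1L & k <= length(bin_edges) - 1L & a < bin_edges[length(bin_edges)]
  counts <- tabulate(k[inbin], length(bin_edges) - 1L)
  structure(list(bin_edges = bin_edges, counts = counts,
                 frequency = if (sum(counts) > 0) counts / sum(counts)
                             else counts * 0,
                 overflow = sum(!inbin)),
            class = "ClusterSizeHistogram")
}

#' @export
print.ClusterSizeHistogram <- function(x, ...) {
  cat("ClusterSizeHistogram:", sum(x$counts), "clusters in",
      length(x$counts), "bins,", x$overflow, "overflow\n")
  invisible(x)
}

#' Small-cluster band frequency
#'
#' Fraction of clusters whose area falls in `[lo, hi)` µm². The default
#' 300–3000 µm² band corresponds to clusters of roughly 1–10 cells; its
#' frequency rises when cells detach and remain in small groups.
#'
#' @param table a `ClusterTable`.
#' @param lo,hi band limits in µm² (half-open `[lo, hi)`).
#' @return fraction in `[0, 1]`; `NA` with a warning for an empty table.
#' @export
band_frequency <- function(table, lo = 300, hi = 3000) {
  stop_if_not(hi > lo, "hi must exceed lo")
  if (nrow(table) == 0) {
    warning("band frequency undefined on an empty cluster table")
    return(NA_real_)
  }
  mean(table$area >= lo & table$area < hi)
}

#' Pooled cluster size distribution
#'
#' Histogram of the concatenated cluster list from several fields or
#' parallel experiments.
#'
#' @param tables list of `ClusterTable`s (>= 1).
#' @param bin_edges strictly increasing bin edges in µm².
#' @return a `ClusterSizeHistogram` of the pooled clusters.
#' @export
pooled_distribution <- function(tables, bin_edges) {
  stop_if_not(is.list(tables) && length(tables) >= 1, "need >= 1 tables")
  size_histogram(data.frame(area = unlist(lapply(tables, `[[`, "area"))),
                 bin_edges)
}
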