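# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' Pad a matrix on all sides
#'
#' @param m numeric matrix.
#' @param r pad width in pixels.
#' @param type `"reflect"` mirrors rows/columns across the edge (edge pixel
#'   included), `"replicate"` repeats the edge pixel.
#' @return padded matrix of dimension `dim(m) + 2 * r`.
#' @keywords internal
#' @noRd
pad_matrix <- function(m, r, type = c("reflect", "replicate")) {
  type <- match.arg(type)
  nr <- nrow(m); nc <- ncol(m)
  stop_if_not(r >= 0, "pad width must be non-negative")
  stop_if_not(r <= nr - 1 && r <= nc - 1 || type == "replicate",
              "reflection pad wider than image")
  idx <- function(n) {
    if (type == "reflect") c(rev(seq_len(min(r, n))), seq_len(n),
                             n + 1 - seq_len(min(r, n)))
    else c(rep(1L, r), seq_len(n), rep(n, r))
  }
  m[idx(nr), idx(nc), drop = FALSE]
}

# Sliding (2r+1)^2 box sum via integral image on an already padded matrix.
# Returns a matrix of the original (unpadded) size.
box_sum_padded <- function(p, r, nr, nc) {
  s <- apply(p, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  s <- rbind(0, cbind(0, s))
  w <- 2L * r + 1L
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  s[i1 + w, j1 + w, drop = FALSE] - s[i1, j1 + w, drop = FALSE] -
    s[i1 + w, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

box_sum <- function(m, r, pad = "reflect") {
  box_sum_padded(pad_matrix(m, r, pad), r, nrow(m), ncol(m))
}

# Binary box morphology with explicit edge policy: dilation treats outside
# the frame as background, erosion as foreground, so full-frame masks are
# fixed points of closing and of the compensation erosion.
bin_dilate <- function(m, r) {
  if (r <= 0) return(m)
  p <- pad_matrix(m, r, "replicate")
  p[c(seq_len(r), nrow(p) - seq_len(r) + 1L), ] <- 0
  p[, c(seq_len(r), ncol(p) - seq_len(r) + 1L)] <- 0
  (box_sum_padded(p, r, nrow(m), ncol(m)) > 0) * 1L
}

bin_erode <- function(m, r) {
  if (r <= 0) return(m)
  p <- pad_matrix(m, r, "replicate")
  p[c(seq_len(r), nrow(p) - seq_len(r) + 1L), ] <- 1
  p[, c(seq_len(r), ncol(p) - seq_len(r) + 1L)] <- 1
  w <- 2L * r + 1L
  (box_sum_padded(p, r, nrow(m), ncol(m)) == w * w) * 1L
}

bin_close <- function(m, r) bin_erode(bin_dilate(m, r), r)

#' Otsu threshold on arbitrary-range data
#'
#' Maximizes between-class variance over a binned histogram; returns a value
#' such that `x > threshold` selects the upper class. Invariant under affine
#' rescaling of `x` (bins are placed over the data range).
#' @keywords internal
#' @noRd
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  stop_if_not(diff(rng) > 0, "cannot threshold constant data")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p); w1 <- 1 - w0
  mu0 <- cumsum(p * mids) / pmax(w0, .Machine$double.eps)
  muT <- sum(p * mids)
  mu1 <- (muT - cumsum(p * mids)) / pmax(w1, .Machine$double.eps)
  bc <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(bc[-n_bins])
  edges[k + 1L]
}

# Mean and SEM by group; single observations report SEM 0.
mean_sem <- function(x) {
  n <- length(x)
  c(mean = mean(x), sem = if (n > 1) sd(x) / sqrt(n) else 0, n = n)
}
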