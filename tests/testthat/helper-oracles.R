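# Independent brute-force oracles used to check the optimized implementations.

iou <- function(a, b) {
  sum(a$pixels & b$pixels) / sum(a$pixels | b$pixels)
}

# population variance of the (2r+1)^2 neighborhood of pixel (i, j), by
# direct enumeration, with symmetric reflection at the frame edge
neighborhood_variance <- function(m, i, j, r) {
  refl <- function(k, n) {
    k[k < 1] <- 1 - k[k < 1]
    k[k > n] <- 2 * n + 1 - k[k > n]
    k
  }
  vals <- as.vector(m[refl(i + (-r:r), nrow(m)), refl(j + (-r:r), ncol(m))])
  mean((vals - mean(vals))^2)
}

# half-open binning by explicit comparison
brute_bin_counts <- function(areas, edges) {
  vapply(seq_len(length(edges) - 1L), function(k)
    sum(areas >= edges[k] & areas < edges[k + 1L]), integer(1))
}

# explicit window enumeration of pooled net displacements
brute_pooled_mean <- function(tracks, duration, stride = 1L) {
  disp <- c()
  for (tr in tracks) {
    t <- tr$t_h
    dt <- median(diff(t))
    for (s in seq(1L, length(t), by = stride)) {
      target <- t[s] + duration
      k <- which.min(abs(t - target))
      if (abs(t[k] - target) <= dt / 2 && k > s)
        disp <- c(disp, sqrt((tr$x_um[k] - tr$x_um[s])^2 +
                             (tr$y_um[k] - tr$y_um[s])^2))
    }
  }
  mean(disp)
}

# normalized perimeter of an a x b ellipse from the arc-length integral
ellipse_ratio_oracle <- function(a, b) {
  per <- 4 * stats::integrate(function(th) sqrt((a * sin(th))^2 + (b * cos(th))^2),
                              0, pi / 2, rel.tol = 1e-10)$value
  per / (2 * sqrt(pi * (pi * a * b)))
}

make_binary <- function(m, ps = 1) binary_mask(m, ps)
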