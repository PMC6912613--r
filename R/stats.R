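# Shared two-sample testing and per-timepoint significance tracks.

#' Two-sample comparison with variance-rule gating
#'
#' Two-sided two-sample t-test. Under the default `f_test` rule an F-test of
#' variance equality at `alpha_var` selects the pooled-variance Student
#' t-test (equality not rejected) or Welch's t-test (rejected). The rule can
#' be forced with `always_pooled` / `always_welch`. Identical degenerate
#' samples (zero spread overall) report `statistic 0, p 1`.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param variance_rule `"f_test"`, `"always_pooled"` or `"always_welch"`.
#' @param alpha_var significance level of the gating F-test (default 0.05).
#' @return list with `statistic` (t), `p_value`, `method_used`
#'   (`"pooled"` or `"welch"`), `df`, and `f_p_value` (NA unless gated).
#' @export
two_sample_test <- function(x, y,
                            variance_rule = c("f_test", "always_pooled",
                                              "always_welch"),
                            alpha_var = 0.05) {
  variance_rule <- match.arg(variance_rule)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stop_if_not(length(x) >= 2 && length(y) >= 2,
              "each sample needs >= 2 finite values")
  if (sd(x) == 0 && sd(y) == 0) {
    # both samples degenerate: equal means are indistinguishable (p = 1),
    # different constant means are trivially separated (p = 0)
    eq <- mean(x) == mean(y)
    return(list(statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p_value = if (eq) 1 else 0, method_used = "pooled",
                df = length(x) + length(y) - 2, f_p_value = NA_real_))
  }
  fp <- NA_real_
  pooled <- switch(variance_rule,
    always_pooled = TRUE,
    always_welch = FALSE,
    f_test = {
      fp <- if (sd(x) == 0 || sd(y) == 0) 0 else var.test(x, y)$p.value
      fp >= alpha_var
    })
  tt <- t.test(x, y, var.equal = pooled)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       method_used = if (pooled) "pooled" else "welch",
       df = unname(tt$parameter), f_p_value = fp)
}

#' Per-timepoint significance track between two conditions
#'
#' Runs [two_sample_test()] independently at every shared time point of two
#' per-field series and flags p < 0.05 and p < 0.01. No multiple-testing
#' correction is applied across time points (the flags annotate a time
#' course rather than test a single hypothesis); this is recorded in the
#' returned metadata.
#'
#' @param seriesA,seriesB numeric matrices, fields x timepoints (columns
#'   aligned between conditions), e.g. the `fields` attribute of
#'   [speed_timeseries()].
#' @param times optional time labels (defaults to column index).
#' @param variance_rule see [two_sample_test()].
#' @return data frame with `time`, `p_value`, `sig05`, `sig01`, `n_a`,
#'   `n_b`; timepoints with fewer than 2 fields on either side are skipped
#'   (`NA`) with a message. Attribute `multiplicity_correction = "none"`.
#' @export
pointwise_significance <- function(seriesA, seriesB, times = NULL,
                                   variance_rule = "f_test") {
  seriesA <- as.matrix(seriesA); seriesB <- as.matrix(seriesB)
  stop_if_not(ncol(seriesA) == ncol(seriesB),
              "conditions must share time points")
  nt <- ncol(seriesA)
  times <- times %||% seq_len(nt)
  stop_if_not(length(times) == nt, "times must match the number of columns")
  p <- rep(NA_real_, nt); na <- nb <- integer(nt)
  skipped <- 0L
  for (j in seq_len(nt)) {
    a <- seriesA[, j]; a <- a[is.finite(a)]
    b <- seriesB[, j]; b <- b[is.finite(b)]
    na[j] <- length(a); nb[j] <- length(b)
    if (length(a) < 2 || length(b) < 2) { skipped <- skipped + 1L; next }
    p[j] <- two_sample_test(a, b, variance_rule = variance_rule)$p_value
  }
  if (skipped > 0)
    message(skipped, " timepoint(s) skipped (< 2 fields per condition)")
  out <- data.frame(time = times, p_value = p,
                    sig05 = !is.na(p) & p < 0.05,
                    sig01 = !is.na(p) & p < 0.01,
                    n_a = na, n_b = nb)
  attr(out, "multiplicity_correction") <- "none"
  out
}
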