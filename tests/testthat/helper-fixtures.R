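# Shared in-code fixtures for the test suite.

# Sum-of-Gaussians spectrum on a uniform descending grid.
gaussian_spectrum <- function(wavenumbers, centers, amps, sigmas) {
  sig <- numeric(length(wavenumbers))
  for (j in seq_along(centers))
    sig <- sig + amps[j] * exp(-(wavenumbers - centers[j])^2 / (2 * sigmas[j]^2))
  sig
}

# Short fingerprint-region grid (keeps per-test cost low).
short_grid <- function() seq(1900, 900, by = -1.928)

# Independent per-window polynomial-fit oracle for Savitzky-Golay filtering:
# at each point, fit a degree-`p` polynomial over the window by least squares
# and evaluate its `m`-th derivative at the point. Edge windows are one-sided.
savgol_oracle <- function(y, window, p, m, ts) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1, i - h), n - window + 1)
    idx <- lo:(lo + window - 1)
    x <- (idx - i) * ts
    fit <- stats::lm.fit(outer(x, 0:p, `^`), y[idx])
    out[i] <- fit$coefficients[m + 1] * factorial(m)
  }
  out
}

# A small panel shared by several files (generated once per test run).
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_panel(n_strains_per_genus = 1, seed = 42)
    cache
  }
})
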