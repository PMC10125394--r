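# Shared fixtures for the fixir test suite. Everything is generated in
# code; no data files.

std_grid <- function() wavenumber_grid()

# A single analytic Gaussian band on the standard grid.
gaussian_spectrum <- function(mu, sigma, amp = 1, grid = std_grid(),
                              offset = 0) {
  ir_spectrum(grid, offset + amp * exp(-((grid$values - mu)^2) /
                                         (2 * sigma^2)))
}

# A silent (all configurable-variability-off) study configuration.
quiet_config <- function(...) {
  study_config(noise_sd = 0, baseline_scale = 0, atmospheric_scale = 0,
               tau_jitter_sd = 0, amp_jitter_sd = 0, ...)
}

# Independent brute-force oracle for the derivative-lobe metrics of an
# analytic Gaussian band: evaluates the analytic first derivative on a
# 100x oversampled axis and reads peak / half-max crossings directly.
gaussian_lobe_oracle <- function(mu, sigma, lo = 1500, hi = 1700) {
  nu <- seq(lo, hi, by = 0.08)
  d <- -(nu - mu) / sigma^2 * exp(-((nu - mu)^2) / (2 * sigma^2))
  peak <- nu[which.max(d)]
  half <- max(d) / 2
  above <- range(nu[d >= half])
  list(peak_location = peak, fwhm = diff(above))
}

# Independent PLS1 oracle via the Krylov-subspace formulation: the
# k-component PLS1 fit equals least squares of y on the scores
# X_c K, K = [v, Av, ..., A^{k-1} v], A = X_c' X_c, v = X_c' y_c.
krylov_pls_oracle <- function(X, y, k, newX) {
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  v <- drop(crossprod(Xc, yc))
  K <- matrix(0, ncol(X), k)
  K[, 1] <- v / sqrt(sum(v^2))
  if (k > 1) {
    A <- crossprod(Xc)
    for (j in 2:k) {
      u <- drop(A %*% K[, j - 1])
      K[, j] <- u / sqrt(sum(u^2))
    }
  }
  B <- Xc %*% K
  beta_k <- qr.solve(qr(B), yc)
  beta <- drop(K %*% beta_k)
  drop(sweep(as.matrix(newX), 2, x_mean) %*% beta) + y_mean
}
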