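# Amide-band deformation metrics: Savitzky-Golay first derivative, peak
# location and FWHM of the Amide I derivative's positive lobe, Amide A peak
# magnitude.

#' Spectral band window
#'
#' @param name band label.
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return Object of class `band_window`.
#' @export
band_window <- function(name, lo, hi) {
  if (lo >= hi) stop("band window must have lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_window")
}

#' Conventional amide band windows
#'
#' Amide I 1600-1700, Amide II 1500-1580, Amide A 3200-3400 and Amide B
#' 3050-3100 cm^-1 — standard literature assignments for protein
#' vibrational bands.
#'
#' @return named list of [band_window()]s.
#' @export
default_band_windows <- function() {
  list(amide_I  = band_window("amide_I", 1600, 1700),
       amide_II = band_window("amide_II", 1500, 1580),
       amide_A  = band_window("amide_A", 3200, 3400),
       amide_B  = band_window("amide_B", 3050, 3100))
}

# Savitzky-Golay convolution weights for the d-th derivative at position
# `at` (offset in samples from the window center), window length w, degree p.
savgol_weights <- function(w, p, d, at = 0) {
  half <- (w - 1) / 2
  z <- (-half):half
  A <- outer(z, 0:p, `^`)
  # row of the pseudo-inverse scaled for the d-th derivative at offset `at`
  G <- solve(crossprod(A), t(A))
  pow <- 0:p
  eval_row <- (pow >= d) * ifelse(pow >= d,
                                  factorial(pow) / factorial(pmax(pow - d, 0)) *
                                    at^(pmax(pow - d, 0)), 0)
  drop(eval_row %*% G)
}

#' Savitzky-Golay first derivative of a spectrum
#'
#' Local least-squares polynomial differentiation: exact for polynomials up
#' to `polyorder`. Interior points use the central filter; each edge point
#' is evaluated from the polynomial fitted to the first (or last) window.
#' Returns dA/d(nu) on the same grid, in AU per cm^-1.
#'
#' @param spectrum an [ir_spectrum()].
#' @param window_pts odd filter length, greater than `polyorder`
#'   (default 9 points = 72 cm^-1 on the standard grid).
#' @param polyorder fitted polynomial degree, at least 1 (default 3).
#' @return the derivative as an [ir_spectrum()] (values may be negative).
#' @export
savgol_first_derivative <- function(spectrum, window_pts = 9, polyorder = 3) {
  if (!is_ir_spectrum(spectrum)) stop("spectrum must be an ir_spectrum")
  if (window_pts %% 2 != 1) stop("window_pts must be odd")
  if (polyorder < 1 || window_pts <= polyorder) {
    stop("need window_pts > polyorder >= 1")
  }
  v <- spectrum$absorbance
  n <- length(v)
  if (window_pts > n) stop("window larger than the spectrum")
  step <- spectrum$grid$step
  half <- (window_pts - 1) / 2
  wc <- savgol_weights(window_pts, polyorder, 1)
  out <- numeric(n)
  # interior: convolution
  for (i in (half + 1):(n - half)) {
    out[i] <- sum(wc * v[(i - half):(i + half)])
  }
  # edges: polynomial fitted to the boundary window, evaluated off-center
  for (j in seq_len(half)) {
    wj <- savgol_weights(window_pts, polyorder, 1, at = j - half - 1)
    out[j] <- sum(wj * v[1:window_pts])
    wj <- savgol_weights(window_pts, polyorder, 1, at = half + 1 - j)
    out[n - j + 1] <- sum(wj * v[(n - window_pts + 1):n])
  }
  ir_spectrum(spectrum$grid, out / step)
}

# Linear-interpolated crossing of `level` between grid points i (above) and
# i-direction (below): returns the wavenumber of the crossing.
interp_crossing <- function(nu, y, i_above, i_below, level) {
  x1 <- nu[i_below]; y1 <- y[i_below]
  x2 <- nu[i_above]; y2 <- y[i_above]
  x1 + (level - y1) * (x2 - x1) / (y2 - y1)
}

#' Peak location and FWHM of a derivative's positive lobe
#'
#' Analyzes the rising-edge (positive) lobe of a band's first derivative
#' inside `window`: the peak is the discrete argmax refined by parabolic
#' interpolation over its 3-point neighborhood; the FWHM is the distance
#' between the two half-maximum crossings of the lobe, each located by
#' linear interpolation between the bracketing grid points. If a half-max
#' crossing falls outside the window the search is extended by up to
#' `extend_pts` grid points before failing.
#'
#' @param deriv a first-derivative [ir_spectrum()] (see
#'   [savgol_first_derivative()]).
#' @param window a [band_window()] inside the grid.
#' @param extend_pts maximum extension beyond the window edge (grid points).
#' @return list with `peak_location` and `fwhm` (both cm^-1).
#' @export
derivative_band_metrics <- function(deriv, window, extend_pts = 5) {
  if (!is_ir_spectrum(deriv)) stop("deriv must be an ir_spectrum")
  nu <- deriv$grid$values
  y <- deriv$absorbance
  inside <- which(nu >= window$lo & nu <= window$hi)
  if (length(inside) < 3) stop("band window contains too few grid points")
  ymax_i <- inside[which.max(y[inside])]
  if (y[ymax_i] <= 0) {
    stop(sprintf(
      "no positive derivative lobe in %s window: non-protein-like spectrum",
      window$name))
  }
  # parabolic refinement of the peak
  peak <- nu[ymax_i]
  ypk <- y[ymax_i]
  if (ymax_i > 1 && ymax_i < length(y)) {
    y1 <- y[ymax_i - 1]; y2 <- y[ymax_i]; y3 <- y[ymax_i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      peak <- nu[ymax_i] + delta * deriv$grid$step
      ypk <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  half <- ypk / 2
  lo_lim <- max(1L, inside[1] - as.integer(extend_pts))
  hi_lim <- min(length(y), inside[length(inside)] + as.integer(extend_pts))
  # walk left
  i <- ymax_i
  while (i > lo_lim && y[i] >= half) i <- i - 1L
  if (y[i] >= half) {
    stop(sprintf("left half-maximum of the %s lobe not found within %d
 points of the window", window$name, extend_pts))
  }
  left <- interp_crossing(nu, y, i + 1L, i, half)
  # walk right
  i <- ymax_i
  while (i < hi_lim && y[i] >= half) i <- i + 1L
  if (y[i] >= half) {
    stop(sprintf("right half-maximum of the %s lobe not found within %d
 points of the window", window$name, extend_pts))
  }
  right <- interp_crossing(nu, y, i - 1L, i, half)
  list(peak_location = peak, fwhm = right - left)
}

#' Peak absorbance magnitude within a band window
#'
#' @param spectrum a preprocessed [ir_spectrum()].
#' @param window a [band_window()].
#' @return maximum absorbance (AU) inside the window.
#' @export
band_peak_magnitude <- function(spectrum, window) {
  if (!is_ir_spectrum(spectrum)) stop("spectrum must be an ir_spectrum")
  nu <- spectrum$grid$values
  inside <- nu >= window$lo & nu <= window$hi
  if (!any(inside)) stop("band window lies outside the grid")
  max(spectrum$absorbance[inside])
}

#' Amide-band deformation features of a tissue spectrum
#'
#' Bundles the three fixation-tracking metrics of a preprocessed
#' representative spectrum: Amide I first-derivative positive-lobe peak
#' location, its FWHM, and the Amide A peak magnitude.
#'
#' @param tissue_spectrum preprocessed [ir_spectrum()] (see
#'   [preprocess_tissue()]).
#' @param windows named list with `amide_I` and `amide_A`
#'   [band_window()]s; default [default_band_windows()].
#' @param window_pts,polyorder Savitzky-Golay settings.
#' @return list of class `band_features`: `amide1_peak_location`,
#'   `amide1_fwhm` (cm^-1), `amideA_peak_magnitude` (AU).
#' @export
extract_features <- function(tissue_spectrum,
                             windows = default_band_windows(),
                             window_pts = 9, polyorder = 3) {
  d <- savgol_first_derivative(tissue_spectrum, window_pts, polyorder)
  m <- derivative_band_metrics(d, windows$amide_I)
  structure(list(amide1_peak_location = m$peak_location,
                 amide1_fwhm = m$fwhm,
                 amideA_peak_magnitude =
                   band_peak_magnitude(tissue_spectrum, windows$amide_A)),
            class = "band_features")
}
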