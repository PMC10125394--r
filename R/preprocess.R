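# Preprocessing chain for MID-IR point spectra: absorbance computation,
# atmospheric compensation, concave rubber-band baseline correction,
# amplitude normalization, spatial averaging.

#' Preprocessing configuration
#'
#' @param baseline_points number of rubber-band support intervals
#'   (default 64).
#' @param baseline_iterations concave rubber-band passes (default 9, the
#'   midpoint of the conventional 8-10).
#' @param atmospheric_reference an [ir_spectrum()] to regress out, or
#'   `NULL` to use the bundled synthetic CO2/water-vapor reference on the
#'   spectrum's own grid.
#' @param normalization only `"global_max"` is implemented: divide by the
#'   maximum over the full wavenumber range.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_points = 64, baseline_iterations = 9,
                              atmospheric_reference = NULL,
                              normalization = "global_max") {
  if (baseline_points < 3) stop("baseline_points must be at least 3")
  if (baseline_iterations < 1) stop("baseline_iterations must be at least 1")
  normalization <- match.arg(normalization, "global_max")
  structure(list(baseline_points = as.integer(baseline_points),
                 baseline_iterations = as.integer(baseline_iterations),
                 atmospheric_reference = atmospheric_reference,
                 normalization = normalization),
            class = "preprocess_config")
}

#' Absorbance from sample and background transmission
#'
#' `A(nu) = -log10(I(nu) / I0(nu))`: the sample's transmitted intensity
#' divided by the transmission of the bare slide, on a decadic log scale.
#'
#' @param sample_transmission,background_transmission [ir_spectrum()]s on
#'   identical grids; the background must be strictly positive everywhere.
#' @return An [ir_spectrum()] of absorbance.
#' @export
compute_absorbance <- function(sample_transmission, background_transmission) {
  if (!is_ir_spectrum(sample_transmission) ||
      !is_ir_spectrum(background_transmission)) {
    stop("both inputs must be ir_spectrum objects")
  }
  if (!grids_identical(sample_transmission$grid,
                       background_transmission$grid)) {
    stop("sample and background grids differ")
  }
  bg <- background_transmission$absorbance
  bad <- which(bg <= 0)
  if (length(bad) > 0) {
    stop(sprintf("background transmission is not positive at %g cm^-1",
                 background_transmission$grid$values[bad[1]]))
  }
  ratio <- sample_transmission$absorbance / bg
  if (any(ratio <= 0)) {
    stop("sample transmission must be positive to form absorbance")
  }
  ir_spectrum(sample_transmission$grid, -log10(ratio))
}

# Atmospheric fitting windows (cm^-1): CO2 band and water-vapor comb.
ATMOS_WINDOWS <- list(c(2300, 2400), c(1400, 1800))

#' Compensate atmospheric absorbers
#'
#' Subtracts `alpha * reference`, where `alpha` is the reference loading
#' estimated by least squares restricted to the atmospheric windows
#' (2300-2400 and 1400-1800 cm^-1). The fit is performed on high-pass
#' filtered signals (residual of a 7-point quadratic local smoother):
#' narrow atmospheric lines survive the filter while the broad protein
#' bands and the scattering baseline that share the 1400-1800 cm^-1 window
#' do not, so they cannot leak into `alpha`. Only the reference component
#' is subtracted, so outside the windows the change is exactly
#' `-alpha * reference`.
#'
#' @param spectrum an [ir_spectrum()].
#' @param reference the atmospheric reference [ir_spectrum()] (same grid);
#'   if identically zero the input is returned unchanged.
#' @return corrected [ir_spectrum()], with the fitted scale in attribute
#'   `"alpha"`.
#' @export
atmospheric_correction <- function(spectrum,
                                   reference = atmospheric_reference(spectrum$grid)) {
  if (!is_ir_spectrum(spectrum) || !is_ir_spectrum(reference)) {
    stop("spectrum and reference must be ir_spectrum objects")
  }
  if (!grids_identical(spectrum$grid, reference$grid)) {
    stop("spectrum and reference grids differ")
  }
  alpha <- atmos_alpha(spectrum$absorbance, reference$absorbance,
                       spectrum$grid$values)
  out <- ir_spectrum(spectrum$grid,
                     spectrum$absorbance - alpha * reference$absorbance)
  attr(out, "alpha") <- alpha
  out
}

# Residual of a w-point local quadratic (Savitzky-Golay) smoother: the
# high-pass component used to isolate narrow atmospheric lines.
highpass_sg <- function(v, w = 7, p = 2) {
  half <- (w - 1) / 2
  z <- (-half):half
  A <- outer(z, 0:p, `^`)
  wt <- solve(crossprod(A), t(A))[1, ]
  sm <- stats::filter(v, rev(wt), sides = 2)
  sm <- as.numeric(sm)
  edge <- is.na(sm)
  sm[edge] <- v[edge]
  v - sm
}

# Least-squares reference loading within the atmospheric windows, fitted
# on high-pass filtered signals.
atmos_alpha <- function(values, ref, nu) {
  if (sum(ref^2) < 1e-12) return(0)
  sel <- Reduce(`|`, lapply(ATMOS_WINDOWS,
                            function(w) nu >= w[1] & nu <= w[2]))
  hr <- highpass_sg(ref)[sel]
  den <- sum(hr^2)
  if (den < 1e-12) return(0)
  hs <- highpass_sg(values)[sel]
  sum(hs * hr) / den
}

# Segment index list for the rubber-band supports: 1..n split into k
# nearly equal contiguous chunks.
baseline_segments <- function(n, k) {
  starts <- unique(round(seq(1, n + 1, length.out = k + 1)))
  lapply(seq_len(length(starts) - 1),
         function(j) starts[j]:(starts[j + 1] - 1))
}

# Lower convex hull (Andrew's monotone chain) of points sorted by x.
# Returns indices of hull vertices.
lower_hull <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  h <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      o <- h[k - 1L]; a <- h[k]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    h[k] <- i
  }
  h[seq_len(k)]
}

# One rubber-band pass on a value vector: support candidates are the
# per-segment minima (plus both end points); the baseline is the linear
# interpolation through their lower convex hull.
rubberband_pass <- function(values, nu, segs) {
  cand <- vapply(segs, function(ix) ix[which.min(values[ix])], integer(1))
  cand <- sort(unique(c(1L, cand, length(values))))
  hull <- lower_hull(nu[cand], values[cand])
  sup <- cand[hull]
  bl <- stats::approx(nu[sup], values[sup], xout = nu, rule = 2)$y
  list(baseline = bl, support = sup)
}

#' Concave rubber-band baseline correction
#'
#' The wavenumber axis is split into `baseline_points` equal segments; each
#' segment's minimum is a support candidate, and one pass subtracts the
#' linear interpolation through the lower convex hull of the candidates.
#' Repeating the pass `baseline_iterations` times on the running corrected
#' signal, accumulating the subtractions, lets the net baseline bend into
#' concave regions that a single convex hull cannot reach ("concave"
#' rubber-band correction). At every support point the baseline does not
#' exceed the spectrum and the corrected value is non-negative.
#'
#' @param spectrum an [ir_spectrum()], at least `baseline_points` long.
#' @param config a [preprocess_config()].
#' @return list with `baseline` and `corrected` [ir_spectrum()]s and the
#'   integer `support` indices of the final pass.
#' @export
rubberband_baseline <- function(spectrum, config = preprocess_config()) {
  if (!is_ir_spectrum(spectrum)) stop("spectrum must be an ir_spectrum")
  nu <- spectrum$grid$values
  n <- length(nu)
  if (n < config$baseline_points) {
    stop(sprintf("spectrum has %d points but %d baseline points requested",
                 n, config$baseline_points))
  }
  segs <- baseline_segments(n, config$baseline_points)
  work <- spectrum$absorbance
  total <- numeric(n)
  sup <- integer(0)
  for (it in seq_len(config$baseline_iterations)) {
    p <- rubberband_pass(work, nu, segs)
    total <- total + p$baseline
    work <- work - p$baseline
    sup <- p$support
  }
  list(baseline = ir_spectrum(spectrum$grid, total),
       corrected = ir_spectrum(spectrum$grid, work),
       support = sup)
}

#' Normalize a spectrum to its global maximum
#'
#' Divides by the maximum over the full wavenumber range, so the output
#' peaks at exactly 1 and is a positive scalar multiple of the input.
#'
#' @param spectrum an [ir_spectrum()] with a positive maximum.
#' @return normalized [ir_spectrum()].
#' @export
normalize_amplitude <- function(spectrum) {
  if (!is_ir_spectrum(spectrum)) stop("spectrum must be an ir_spectrum")
  m <- max(spectrum$absorbance)
  if (m <= 0) stop("cannot normalize: spectrum maximum is not positive")
  ir_spectrum(spectrum$grid, spectrum$absorbance / m)
}

#' Pointwise mean of spectra on a common grid
#'
#' @param spectra non-empty list of [ir_spectrum()]s sharing one grid.
#' @return the mean [ir_spectrum()].
#' @export
average_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L) {
    stop("spectra must be a non-empty list")
  }
  g <- spectra[[1]]$grid
  for (s in spectra) {
    if (!is_ir_spectrum(s)) stop("all elements must be ir_spectrum objects")
    if (!grids_identical(s$grid, g)) stop("spectra are on different grids")
  }
  vals <- rowMeans(vapply(spectra, function(s) s$absorbance,
                          numeric(length(g$values))))
  ir_spectrum(g, vals)
}

# Fast matrix path used by preprocess_tissue / metric maps: rows are
# spectra. Applies atmospheric correction, rubber-band baseline and
# normalization per row; no averaging.
preprocess_matrix <- function(mat, grid, config) {
  nu <- grid$values
  ref <- config$atmospheric_reference
  if (is.null(ref)) ref <- atmospheric_reference(grid)
  if (!grids_identical(ref$grid, grid)) {
    stop("atmospheric reference grid does not match the spectra")
  }
  refv <- ref$absorbance
  sel <- Reduce(`|`, lapply(ATMOS_WINDOWS,
                            function(w) nu >= w[1] & nu <= w[2]))
  hr <- highpass_sg(refv)[sel]
  den <- sum(hr^2)
  segs <- baseline_segments(length(nu), config$baseline_points)
  out <- mat
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    if (den > 1e-12) {
      v <- v - (sum(highpass_sg(v)[sel] * hr) / den) * refv
    }
    for (it in seq_len(config$baseline_iterations)) {
      p <- rubberband_pass(v, nu, segs)
      v <- v - p$baseline
    }
    m <- max(v)
    if (m <= 0) stop("flat/empty tissue spectrum: non-positive maximum")
    out[i, ] <- v / m
  }
  out
}

#' Preprocess a tissue record into one representative spectrum
#'
#' Per point spectrum: atmospheric correction, concave rubber-band baseline
#' correction, amplitude normalization; then the spatial average over all
#' point spectra of the slide — the fixed chain order of the acquisition
#' software.
#'
#' @param record a [tissue_record()].
#' @param config a [preprocess_config()].
#' @return the averaged, preprocessed [ir_spectrum()].
#' @export
preprocess_tissue <- function(record, config = preprocess_config()) {
  if (!inherits(record, "tissue_record")) {
    stop("record must be a tissue_record")
  }
  pp <- preprocess_matrix(record$spectra, record$grid, config)
  ir_spectrum(record$grid, colMeans(pp))
}
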