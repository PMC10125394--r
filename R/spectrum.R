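#' Wavenumber grid for MID-IR spectra
#'
#' The standard acquisition axis: `start`..`stop` cm^-1 sampled every `step`
#' cm^-1. The default (900-4000 cm^-1 at 8 cm^-1) gives the points
#' `900 + 8k`, `k = 0..387`; the last point is 3996 cm^-1 because
#' `(4000 - 900) / 8` is not integral and the step is kept exact.
#'
#' @param start first wavenumber (cm^-1).
#' @param stop upper limit (cm^-1); the grid never exceeds it.
#' @param step spectral resolution, delta-nu (cm^-1).
#' @return An object of class `wavenumber_grid`: list with `start`, `stop`,
#'   `step` and the ascending `values` vector.
#' @export
#' @examples
#' g <- wavenumber_grid()
#' length(g$values)   # 388
#' range(g$values)    # 900 3996
wavenumber_grid <- function(start = 900, stop = 4000, step = 8) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step) ||
      length(start) != 1L || length(stop) != 1L || length(step) != 1L) {
    stop("start, stop and step must be scalar numerics")
  }
  if (step <= 0) stop("step must be positive")
  if (stop <= start) stop("stop must exceed start")
  values <- seq(start, stop, by = step)
  structure(list(start = start, stop = stop, step = step, values = values),
            class = "wavenumber_grid")
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %g-%g cm^-1, step %g cm^-1 (%d points)\n",
              x$values[1], x$values[length(x$values)], x$step,
              length(x$values)))
  invisible(x)
}

is_wavenumber_grid <- function(x) inherits(x, "wavenumber_grid")

grids_identical <- function(a, b) {
  length(a$values) == length(b$values) &&
    isTRUE(all.equal(a$values, b$values, tolerance = 1e-10))
}

#' A single MID-IR absorbance spectrum
#'
#' @param grid a [wavenumber_grid()].
#' @param absorbance numeric vector of absorbance values (AU), one per grid
#'   point; all finite.
#' @return Object of class `ir_spectrum` with fields `grid` and `absorbance`.
#' @export
ir_spectrum <- function(grid, absorbance) {
  if (!is_wavenumber_grid(grid)) stop("grid must be a wavenumber_grid")
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(grid$values)) {
    stop(sprintf("absorbance length (%d) does not match grid length (%d)",
                 length(absorbance), length(grid$values)))
  }
  if (!all(is.finite(absorbance))) stop("absorbance values must all be finite")
  structure(list(grid = grid, absorbance = absorbance), class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %g-%g cm^-1, max %.4g AU\n",
              length(x$absorbance), x$grid$values[1],
              x$grid$values[length(x$grid$values)], max(x$absorbance)))
  invisible(x)
}

is_ir_spectrum <- function(x) inherits(x, "ir_spectrum")

# Coerce an ir_spectrum (or bare numeric on a supplied grid) to numeric values
spectrum_values <- function(x) {
  if (is_ir_spectrum(x)) x$absorbance else as.numeric(x)
}

#' One tissue slide's worth of spectra plus metadata
#'
#' A slide-level record: all point spectra imaged across one cut of a tissue
#' block, the known fixation time (if any), and optional IHC percent
#' positivity per marker.
#'
#' @param tissue_id,replicate_id identifiers (tissue block, and cut within
#'   the block).
#' @param fixation_time hours in formalin; `NA` for unknown specimens.
#' @param spectra numeric matrix, one row per imaged region, one column per
#'   wavenumber of `grid`.
#' @param grid the shared [wavenumber_grid()].
#' @param ihc optional named numeric vector of percent positivity per marker.
#' @return Object of class `tissue_record`.
#' @export
tissue_record <- function(tissue_id, replicate_id, fixation_time, spectra,
                          grid, ihc = NULL) {
  if (!is_wavenumber_grid(grid)) stop("grid must be a wavenumber_grid")
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(grid$values)) {
    stop("spectra must have one column per grid wavenumber")
  }
  if (nrow(spectra) < 1L) stop("a tissue record needs at least one spectrum")
  if (!is.na(fixation_time) && fixation_time < 0) {
    stop("fixation_time must be non-negative")
  }
  structure(list(tissue_id = as.character(tissue_id),
                 replicate_id = as.character(replicate_id),
                 fixation_time = fixation_time,
                 spectra = spectra, grid = grid, ihc = ihc),
            class = "tissue_record")
}

#' @export
print.tissue_record <- function(x, ...) {
  cat(sprintf("<tissue_record> %s/%s, t = %s h, %d spectra x %d points\n",
              x$tissue_id, x$replicate_id,
              ifelse(is.na(x$fixation_time), "?", format(x$fixation_time)),
              nrow(x$spectra), ncol(x$spectra)))
  invisible(x)
}
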