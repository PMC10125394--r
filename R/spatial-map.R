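# Whole-organ fixation mapping: per-pixel band metrics and under-fixed
# region flagging.

METRIC_NAMES <- c("amide1_deriv_peak", "amide1_deriv_fwhm", "amideA_magnitude")

#' Rasterize a band metric over a spectral grid
#'
#' Applies the per-spectrum preprocessing chain (atmospheric correction,
#' rubber-band baseline, normalization) and the requested band metric to
#' every tissue pixel of a [simulate_tonsil_grid()]-style raster.
#'
#' @param grid a `spectral_grid`.
#' @param metric_name one of `"amide1_deriv_peak"`, `"amide1_deriv_fwhm"`,
#'   `"amideA_magnitude"`.
#' @param preprocess a [preprocess_config()].
#' @param windows band windows, default [default_band_windows()].
#' @return Object of class `metric_map`: `metric_name`, `values` (matrix,
#'   `NA` off tissue), `mask`, `pixel_mm`.
#' @export
compute_metric_map <- function(grid, metric_name,
                               preprocess = preprocess_config(),
                               windows = default_band_windows()) {
  if (!inherits(grid, "spectral_grid")) stop("grid must be a spectral_grid")
  metric_name <- match.arg(metric_name, METRIC_NAMES)
  values <- matrix(NA_real_, grid$shape[1], grid$shape[2])
  idx <- which(grid$tissue_mask)
  if (length(idx) > 0) {
    pp <- preprocess_matrix(grid$spectra, grid$grid, preprocess)
    v <- numeric(length(idx))
    for (i in seq_along(idx)) {
      s <- ir_spectrum(grid$grid, pp[i, ])
      v[i] <- switch(metric_name,
        amide1_deriv_peak =
          derivative_band_metrics(savgol_first_derivative(s),
                                  windows$amide_I)$peak_location,
        amide1_deriv_fwhm =
          derivative_band_metrics(savgol_first_derivative(s),
                                  windows$amide_I)$fwhm,
        amideA_magnitude = band_peak_magnitude(s, windows$amide_A))
    }
    values[idx] <- v
  }
  structure(list(metric_name = metric_name, values = values,
                 mask = grid$tissue_mask, pixel_mm = grid$pixel_mm),
            class = "metric_map")
}

# 4-connected component labelling of a logical raster (two-pass would do;
# rasters are small, so simple BFS flood fill).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L
      cl <- (p - 1L) %/% nr + 1L
      for (nb in list(c(r - 1L, cl), c(r + 1L, cl),
                      c(r, cl - 1L), c(r, cl + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= ncol(mask)) {
          q <- (nb[2] - 1L) * nr + nb[1]
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Drop connected components smaller than min_px.
clean_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Flag under-fixed tissue regions on a metric map
#'
#' A pixel is flagged when its metric lies on the unfixed side of
#' `reference_unfixed + threshold_frac * (reference_fixed -
#' reference_unfixed)`. Components smaller than `min_component_px` pixels
#' are removed as noise. The reference values default sensibly to the
#' study-level mean metrics of fully fixed and unfixed cohorts.
#'
#' @param map a [compute_metric_map()] result.
#' @param reference_fixed_value,reference_unfixed_value metric values of
#'   fully fixed / unfixed tissue; must differ.
#' @param threshold_frac position of the decision threshold between the
#'   references (default 0.5 = midpoint).
#' @param min_component_px morphological cleanup size (default 5).
#' @return list with `mask` (logical raster) and `underfixed_fraction`
#'   (flagged / tissue pixels).
#' @export
underfixed_mask <- function(map, reference_fixed_value,
                            reference_unfixed_value, threshold_frac = 0.5,
                            min_component_px = 5) {
  if (!inherits(map, "metric_map")) stop("map must be a metric_map")
  if (reference_fixed_value == reference_unfixed_value) {
    stop("fixed and unfixed reference values must differ")
  }
  thr <- reference_unfixed_value +
    threshold_frac * (reference_fixed_value - reference_unfixed_value)
  if (reference_fixed_value > reference_unfixed_value) {
    flagged <- !is.na(map$values) & map$values < thr
  } else {
    flagged <- !is.na(map$values) & map$values > thr
  }
  flagged <- clean_small_components(flagged, min_component_px)
  n_tissue <- sum(map$mask)
  list(mask = flagged,
       underfixed_fraction = if (n_tissue > 0) sum(flagged) / n_tissue else 0)
}

# Blue-to-red false-color ramp on [0, 1]; NA -> black.
falsecolor <- function(z) {
  ramp <- grDevices::colorRamp(c("#10104f", "#2166ac", "#67a9cf", "#f7f7a0",
                                 "#ef8a62", "#b2182b"))
  rgb <- matrix(0, length(z), 3)
  ok <- !is.na(z)
  if (any(ok)) rgb[ok, ] <- ramp(pmin(1, pmax(0, z[ok]))) / 255
  rgb
}

#' Render metric maps as false-color images
#'
#' Writes one plain-text portable pixmap (PPM, P3) per map. All maps of the
#' same metric share one color scale across the series so a map series is
#' visually comparable; identical maps produce byte-identical files. A
#' scale-bar annotation (2 mm, from `pixel_mm`) is drawn along the bottom
#' edge.
#'
#' @param maps non-empty list of [compute_metric_map()] results.
#' @param out_dir output directory (created if missing).
#' @param names file stems; default `map_01` ...
#' @return invisible character vector of file paths.
#' @export
render_maps <- function(maps, out_dir, names = NULL) {
  if (length(maps) == 0L) stop("no maps to render")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(names)) names <- sprintf("map_%02d", seq_along(maps))
  limits <- list()
  for (m in maps) {
    v <- m$values[!is.na(m$values)]
    lim <- limits[[m$metric_name]]
    limits[[m$metric_name]] <-
      if (is.null(lim)) range(v) else range(c(lim, v))
  }
  paths <- character(length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    lim <- limits[[m$metric_name]]
    span <- if (diff(lim) > 0) diff(lim) else 1
    z <- (m$values - lim[1]) / span
    rgb <- falsecolor(as.vector(z))
    img <- array(0, dim = c(nrow(z), ncol(z), 3))
    for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], nrow(z), ncol(z))
    # scale bar: 2 mm of white pixels along the bottom edge
    bar_px <- min(ncol(z), max(1L, round(2 / m$pixel_mm)))
    img[nrow(z), seq_len(bar_px), ] <- 1
    paths[i] <- file.path(out_dir, paste0(names[i], ".ppm"))
    write_pnm(img, paths[i])
  }
  invisible(paths)
}
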