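# Synthetic brightfield IHC fixtures: a hematoxylin-counterstained tissue
# blob on a white slide with a pale stroma region excluded from analysis
# and DAB-brown positive pixels placed, in spatial clusters, to hit a
# requested percent positivity exactly.

# Expected percent positivity as a function of fixation time.
ihc_curve_params <- list(
  bcl2  = list(kind = "saturating", base = 8,  max = 55, tau = 6),
  foxp3 = list(kind = "saturating", base = 2,  max = 14, tau = 8),
  ki67  = list(kind = "step",       floor_frac = 0.15, max = 65, tau = 0.35)
)

#' Expected IHC percent positivity versus fixation time
#'
#' Epitope availability of fixation-labile markers (bcl-2, FOXP3) rises
#' steadily with formalin exposure and is anchored so the 24 h value equals
#' the configured maximum exactly; ki-67 is fixation-robust, reaching its
#' plateau within about an hour of fixation.
#'
#' @param marker one of `"bcl2"`, `"ki67"`, `"foxp3"`.
#' @param t fixation time(s) in hours, non-negative.
#' @return expected percent positivity in `[0, 100]`, same length as `t`.
#' @export
#' @examples
#' ihc_positivity_curve("bcl2", c(0, 6, 24))
ihc_positivity_curve <- function(marker, t) {
  marker <- tolower(gsub("[^a-z0-9]", "", tolower(marker)))
  if (!marker %in% names(ihc_curve_params)) {
    stop(sprintf("unknown marker '%s' (known: %s)", marker,
                 paste(names(ihc_curve_params), collapse = ", ")))
  }
  if (any(t < 0)) stop("fixation time must be non-negative")
  p <- ihc_curve_params[[marker]]
  norm24 <- 1 - exp(-24 / p$tau)
  s <- (1 - exp(-t / p$tau)) / norm24
  if (p$kind == "saturating") {
    p$base + (p$max - p$base) * s
  } else {
    p$max * (p$floor_frac + (1 - p$floor_frac) * s)
  }
}

# Smooth clustered random field on given pixel indices: sum of Gaussian
# bumps at random in-mask locations.
cluster_field <- function(coords, n_bumps, sigma_px) {
  field <- numeric(nrow(coords))
  centers <- coords[sample.int(nrow(coords), n_bumps, replace = TRUE), ,
                    drop = FALSE]
  w <- stats::runif(n_bumps, 0.5, 1.5)
  for (b in seq_len(n_bumps)) {
    field <- field + w[b] * exp(-((coords[, 1] - centers[b, 1])^2 +
                                  (coords[, 2] - centers[b, 2])^2) /
                                  (2 * sigma_px^2))
  }
  field + stats::rnorm(length(field), sd = 1e-3)  # break threshold ties
}

#' Simulate a brightfield IHC image with known ground truth
#'
#' White background; an elliptical tissue blob of hematoxylin-blue pixels;
#' a pale low-saturation "stroma" wedge inside the blob (excluded from the
#' active region); DAB-brown positive pixels placed as spatial clusters so
#' that exactly `round(percent_positive/100 * |active|)` active pixels are
#' positive (always within 0.5 points of the request).
#'
#' @param percent_positive target percent positivity in `[0, 100]`.
#' @param shape integer c(rows, cols).
#' @param seed integer RNG seed.
#' @return list with `image` (rows x cols x 3 array in `[0, 1]`),
#'   `active_mask`, `positive_mask`, `stroma_mask` (logical matrices) and
#'   `achieved_percent`.
#' @export
simulate_ihc_image <- function(percent_positive, shape = c(256, 256),
                               seed = 1L) {
  if (!is.numeric(percent_positive) || length(percent_positive) != 1L ||
      is.na(percent_positive) || percent_positive < 0 ||
      percent_positive > 100) {
    stop("percent_positive must be a single value in [0, 100]")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  rows <- as.integer(shape[1]); cols <- as.integer(shape[2])
  blob <- default_tissue_mask(rows, cols)

  # stroma: an off-center elliptical wedge inside the blob
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  stroma <- blob & (((rr - 0.35 * rows) / (0.16 * rows))^2 +
                    ((cc - 0.62 * cols) / (0.20 * cols))^2 <= 1)
  active <- blob & !stroma

  n_active <- sum(active)
  n_pos <- round(percent_positive / 100 * n_active)
  positive <- matrix(FALSE, rows, cols)
  if (n_pos > 0) {
    coords <- which(active, arr.ind = TRUE)
    f <- cluster_field(coords, n_bumps = 25,
                       sigma_px = 0.06 * min(rows, cols))
    thr <- sort(f, decreasing = TRUE)[n_pos]
    sel <- f >= thr
    if (sum(sel) > n_pos) sel[which(sel)[seq_len(sum(sel) - n_pos)]] <- FALSE
    positive[coords[sel, , drop = FALSE]] <- TRUE
  }

  img <- array(0, dim = c(rows, cols, 3))
  paint <- function(mask, rgb, jit = 0.03) {
    n <- sum(mask)
    if (n == 0) return()
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- pmin(1, pmax(0, rgb[ch] + stats::rnorm(n, sd = jit)))
      img[, , ch] <<- plane
    }
  }
  paint(!blob, c(0.975, 0.975, 0.975), jit = 0.008)       # slide background
  paint(active & !positive, c(0.42, 0.42, 0.72))          # hematoxylin blue
  paint(positive, c(0.45, 0.28, 0.12))                    # DAB brown
  paint(stroma, c(0.93, 0.87, 0.89), jit = 0.012)         # pale stroma

  list(image = img, active_mask = active, positive_mask = positive,
       stroma_mask = stroma,
       achieved_percent = 100 * n_pos / n_active)
}
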