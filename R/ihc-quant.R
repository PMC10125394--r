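# Brightfield IHC quantitation: tissue segmentation, DAB positivity by
# stain unmixing, percent positivity, hot-spot density maps, normalized
# expression curves and a rank-sum test.

# Per-pixel luminance and saturation of an RGB array in [0, 1].
pixel_luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
pixel_saturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

#' Segment analyzable tissue in a brightfield IHC image
#'
#' Background (bare slide, glass, coverslip edges) is excluded by a
#' luminance criterion applied symmetrically to very bright and very dark
#' unsaturated pixels; stroma/connective tissue is excluded by low stain
#' saturation combined with low local texture (stained tissue is both
#' chromatic and granular). The rules are stand-ins for vendor software and
#' are validated against [simulate_ihc_image()] ground truth.
#'
#' @param image rows x cols x 3 RGB array in `[0, 1]`.
#' @param lum_hi,lum_lo background luminance cutoffs.
#' @param sat_min minimum stain saturation for analyzable tissue.
#' @param texture_sd local (3x3) luminance standard deviation below which a
#'   pale region counts as stroma.
#' @return list of class `segmentation_result`: `active_mask`,
#'   `excluded_mask`, `positive_mask` (empty until
#'   [classify_positive()]).
#' @export
segment_tissue <- function(image, lum_hi = 0.90, lum_lo = 0.10,
                           sat_min = 0.18, texture_sd = 0.04) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an rows x cols x 3 RGB array")
  }
  lum <- pixel_luminance(image)
  sat <- pixel_saturation(image)
  # chroma (max - min), not relative saturation, for the dark branch:
  # relative saturation is numerically unstable near black
  chroma <- pmax(image[, , 1], image[, , 2], image[, , 3]) -
    pmin(image[, , 1], image[, , 2], image[, , 3])
  background <- (lum >= lum_hi & sat < sat_min) |
    (lum <= lum_lo & chroma < 0.1)
  tissue <- !background
  # stroma: pale (low saturation) and smooth (low local texture)
  tex <- local_sd3(lum)
  stroma <- tissue & sat < sat_min & tex < texture_sd
  active <- tissue & !stroma
  structure(list(active_mask = active,
                 excluded_mask = background | stroma,
                 positive_mask = matrix(FALSE, nrow(lum), ncol(lum))),
            class = "segmentation_result")
}

# 3x3 neighborhood standard deviation (edge-replicated).
local_sd3 <- function(m) {
  pad <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  acc <- matrix(0, nrow(m), ncol(m))
  acc2 <- matrix(0, nrow(m), ncol(m))
  for (dr in 0:2) for (dc in 0:2) {
    w <- pad[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))]
    acc <- acc + w
    acc2 <- acc2 + w^2
  }
  sqrt(pmax(0, acc2 / 9 - (acc / 9)^2))
}

# Standard H-DAB optical-density stain vectors (unit norm).
HDAB_VECTORS <- local({
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.777)
  rbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)))
})

#' Classify biomarker-positive pixels by stain unmixing
#'
#' Converts RGB to per-channel optical density `OD = -log10(I)` and unmixes
#' it onto fixed hematoxylin and DAB stain vectors (least squares); a pixel
#' within the active mask is positive when its DAB density exceeds
#' `od_threshold`. Optical density is ratio-based, so uniform brightness
#' changes barely move the result.
#'
#' @param image RGB array in `[0, 1]`.
#' @param active_mask logical matrix from [segment_tissue()].
#' @param od_threshold DAB optical-density cutoff (default 0.15).
#' @param stain_vectors 2 x 3 matrix of unit OD vectors (hematoxylin, DAB).
#' @return logical `positive_mask` (subset of `active_mask`).
#' @export
classify_positive <- function(image, active_mask, od_threshold = 0.15,
                              stain_vectors = HDAB_VECTORS) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be an rows x cols x 3 RGB array")
  }
  if (!any(active_mask)) {
    warning("empty active mask: no pixels to classify")
    return(active_mask)
  }
  idx <- which(active_mask)
  od <- cbind(-log10(pmax(image[, , 1][idx], 1e-4)),
              -log10(pmax(image[, , 2][idx], 1e-4)),
              -log10(pmax(image[, , 3][idx], 1e-4)))
  # least-squares stain concentrations: od ~ conc %*% stain_vectors
  M <- stain_vectors
  conc <- od %*% t(M) %*% solve(M %*% t(M))
  dab <- conc[, 2]
  hem <- conc[, 1]
  positive <- active_mask
  positive[] <- FALSE
  positive[idx[dab > od_threshold & dab > hem]] <- TRUE
  positive
}

#' Percent positivity of a segmentation
#'
#' @param seg a `segmentation_result` with `positive_mask` filled in.
#' @return `100 * |positive| / |active|`.
#' @export
percent_positivity <- function(seg) {
  n_active <- sum(seg$active_mask)
  if (n_active == 0) stop("empty active mask")
  100 * sum(seg$positive_mask & seg$active_mask) / n_active
}

#' Hot-spot density map of biomarker expression
#'
#' Local density of positive pixels via a uniform circular-kernel
#' convolution, masked to the analyzed tissue.
#'
#' @param seg a `segmentation_result`.
#' @param kernel_radius_px kernel radius in pixels, at least 1.
#' @return numeric raster in `[0, 1]` (`NA` off tissue).
#' @export
hotspot_map <- function(seg, kernel_radius_px = 10) {
  if (kernel_radius_px < 1) stop("kernel radius must be at least 1")
  r <- as.integer(kernel_radius_px)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r^2, ]
  pos <- seg$positive_mask
  nr <- nrow(pos); nc <- ncol(pos)
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  inmask <- seg$active_mask
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    rs0 <- rs - dr; cs0 <- cs - dc
    num[rs0, cs0] <- num[rs0, cs0] + pos[rs, cs]
    den[rs0, cs0] <- den[rs0, cs0] + inmask[rs, cs]
  }
  out <- matrix(NA_real_, nr, nc)
  ok <- inmask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Normalize per-marker expression to the 24-hour group
#'
#' @param records data.frame with columns `fixation_time` and
#'   `percent_positive` for one marker.
#' @return data.frame of `fixation_time`, `mean_positive`, `normalized`
#'   (24 h group identically 1).
#' @export
normalize_to_max <- function(records) {
  if (!all(c("fixation_time", "percent_positive") %in% names(records))) {
    stop("records needs fixation_time and percent_positive columns")
  }
  means <- tapply(records$percent_positive, records$fixation_time, mean)
  times <- as.numeric(names(means))
  if (!any(times == 24)) stop("no 24 h group to normalize against")
  ref <- means[times == 24]
  data.frame(fixation_time = times, mean_positive = as.numeric(means),
             normalized = as.numeric(means) / as.numeric(ref))
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact enumeration of the permutation distribution of the rank sum when
#' `n + m <= 12` (ties handled naturally by permuting the observed pooled
#' values); otherwise the normal approximation with tie correction and
#' continuity correction. Identical groups give p = 1.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param method `"auto"` (exact when `n + m <= 12`), `"exact"`, or
#'   `"normal"`.
#' @return two-sided p-value.
#' @export
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))  # 0.1 by exact enumeration
ranksum_test <- function(group_a, group_b,
                         method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  n <- length(group_a); m <- length(group_b)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1L) return(1)
  rk <- rank(pooled)
  w_obs <- sum(rk[seq_len(n)])           # rank sum of group A
  use_exact <- switch(method, auto = n + m <= 12, exact = TRUE,
                      normal = FALSE)
  if (use_exact) {
    combos <- utils::combn(n + m, n)
    w_all <- colSums(matrix(rk[combos], nrow = n))
    eps <- 1e-9
    # two-sided: double the smaller tail (capped at 1)
    p_lo <- mean(w_all <= w_obs + eps)
    p_hi <- mean(w_all >= w_obs - eps)
    min(1, 2 * min(p_lo, p_hi))
  } else {
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}
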