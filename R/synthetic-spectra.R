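#' Gaussian band with saturating fixation kinetics
#'
#' Each spectral band is a Gaussian whose center, width and amplitude relax
#' toward an asymptote as formalin crosslinking proceeds. With
#' `f(t) = 1 - exp(-t / tau)`:
#' \deqn{\mu(t) = \mu_0 + \Delta\mu f(t), \quad
#'       \sigma(t) = \sigma_0 + \Delta\sigma f(t), \quad
#'       a(t) = a_0 (1 - g\, f(t))}
#' A negative amplitude gain `g` therefore models a band that *grows* with
#' fixation (the Amide A default).
#'
#' @param name band label.
#' @param center0 unfixed band center mu0 (cm^-1).
#' @param center_shift asymptotic center shift delta-mu (cm^-1).
#' @param width0 unfixed Gaussian sigma (cm^-1), positive.
#' @param width_gain asymptotic sigma increase (cm^-1).
#' @param amp0 unfixed amplitude (absorbance AU), positive.
#' @param amp_gain fractional amplitude loss at full fixation (negative =
#'   gain).
#' @param tau saturation time constant (hours), positive.
#' @return Object of class `band_model`.
#' @export
band_model <- function(name, center0, center_shift = 0, width0 = 20,
                       width_gain = 0, amp0 = 1, amp_gain = 0, tau = 4) {
  if (width0 <= 0) stop("width0 must be positive")
  if (tau <= 0) stop("tau must be positive")
  if (amp0 <= 0) stop("amp0 must be positive")
  structure(list(name = name, center0 = center0, center_shift = center_shift,
                 width0 = width0, width_gain = width_gain, amp0 = amp0,
                 amp_gain = amp_gain, tau = tau),
            class = "band_model")
}

#' Default band set of the synthetic tissue spectrum
#'
#' Five bands: Amide I (1626 cm^-1, shifting +8 cm^-1 and broadening
#' sigma 22 to 27 cm^-1 with fixation, amplitude falling 15%), Amide II
#' (1545 cm^-1, mild deformation), Amide A (3290 cm^-1, amplitude growing
#' 30% with fixation), and two fixation-inert bystanders: a carbohydrate /
#' nucleic-acid band at 1080 cm^-1 and the CH-stretch band at 2925 cm^-1.
#' All parameters are conventional literature positions; the fixation
#' responses reproduce the observed trends (upward Amide I shift, wider
#' derivative lobe, falling Amide I amplitude, growing Amide A), not any
#' measured chemistry. The bands relax on distinct kinetic timescales
#' (Amide II fastest, Amide A slowest) -- formalin fixation is a sequence
#' of chemistries (methylol adduct formation, cross-link formation,
#' cross-link maturation) rather than one first-order process, and a
#' multi-timescale spectrum is what makes late fixation times (12 h vs
#' 24 h) spectroscopically resolvable at all.
#'
#' @return list of [band_model()] objects.
#' @export
default_band_set <- function() {
  list(
    band_model("amide_I",  1626, center_shift = 8, width0 = 22,
               width_gain = 5, amp0 = 1.00, amp_gain = 0.15, tau = 4),
    band_model("amide_II", 1545, center_shift = 3, width0 = 18,
               width_gain = 2, amp0 = 0.60, amp_gain = 0.05, tau = 2.5),
    band_model("amide_A",  3290, center_shift = 0, width0 = 60,
               width_gain = 0, amp0 = 0.45, amp_gain = -0.30, tau = 8),
    band_model("carb_1080", 1080, amp0 = 0.30, width0 = 30),
    band_model("ch_2925",   2925, amp0 = 0.35, width0 = 35)
  )
}

#' Configuration of a synthetic differential-fixation study
#'
#' Defaults mirror the printed study design: fixation times
#' 0/1/2/4/6/12/24 h, 15 tissues per time (105 tissues), each block cut in
#' duplicate (210 slide-level records), about 100 imaged regions per slide.
#'
#' @param fixation_times strictly increasing non-negative hours.
#' @param tissues_per_time,replicates_per_tissue,regions_per_slide counts,
#'   all at least 1.
#' @param grid a [wavenumber_grid()].
#' @param noise_sd white-noise standard deviation (AU). The default 0.002,
#'   together with the jitter defaults below, is calibrated so the default
#'   study supports fixation-time recovery at the accuracy the method is
#'   known to reach on real tonsil spectra (holdout MAE about 1 h, safely
#'   inside the published 1.4 h bound for typical seeds).
#' @param baseline_scale scattering-baseline magnitude (AU).
#' @param atmospheric_scale atmospheric-contamination magnitude (AU).
#' @param tau_jitter_sd,amp_jitter_sd lognormal sd of per-tissue random
#'   effects on band time constants and amplitudes; partially fixed samples
#'   inherit most of the resulting variability.
#' @param seed integer RNG seed for reproducible studies.
#' @return Object of class `study_config`.
#' @export
study_config <- function(fixation_times = c(0, 1, 2, 4, 6, 12, 24),
                         tissues_per_time = 15,
                         replicates_per_tissue = 2,
                         regions_per_slide = 100,
                         grid = wavenumber_grid(),
                         noise_sd = 0.002,
                         baseline_scale = 0.2,
                         atmospheric_scale = 0.05,
                         tau_jitter_sd = 0.012,
                         amp_jitter_sd = 0.003,
                         seed = 1L) {
  if (any(fixation_times < 0)) stop("fixation_times must be non-negative")
  if (length(fixation_times) > 1 && any(diff(fixation_times) <= 0)) {
    stop("fixation_times must be strictly increasing")
  }
  counts <- c(tissues_per_time, replicates_per_tissue, regions_per_slide)
  if (any(counts < 1)) stop("all counts must be at least 1")
  if (!is_wavenumber_grid(grid)) stop("grid must be a wavenumber_grid")
  if (noise_sd < 0 || baseline_scale < 0 || atmospheric_scale < 0) {
    stop("noise/baseline/atmospheric scales must be non-negative")
  }
  structure(list(fixation_times = fixation_times,
                 tissues_per_time = as.integer(tissues_per_time),
                 replicates_per_tissue = as.integer(replicates_per_tissue),
                 regions_per_slide = as.integer(regions_per_slide),
                 grid = grid, noise_sd = noise_sd,
                 baseline_scale = baseline_scale,
                 atmospheric_scale = atmospheric_scale,
                 tau_jitter_sd = tau_jitter_sd,
                 amp_jitter_sd = amp_jitter_sd,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Saturation factor f(t) = 1 - exp(-t/tau)
saturation <- function(t, tau) 1 - exp(-t / tau)

# Noise-free band-sum absorbance at wavenumbers nu for fixation time t.
# `bands` may carry per-tissue jittered parameters already.
band_sum <- function(nu, t, bands) {
  a <- numeric(length(nu))
  for (b in bands) {
    f <- saturation(t, b$tau)
    mu <- b$center0 + b$center_shift * f
    sg <- b$width0 + b$width_gain * f
    am <- b$amp0 * (1 - b$amp_gain * f)
    a <- a + am * exp(-((nu - mu)^2) / (2 * sg^2))
  }
  a
}

#' Bundled synthetic atmospheric reference spectrum
#'
#' Narrow CO2 doublet near 2350 cm^-1 plus a rotational water-vapor line
#' comb across 1400-1800 cm^-1, max-normalized. Used both by the generator
#' (contamination shape) and as the default reference of
#' [atmospheric_correction()]. Deterministic: no RNG.
#'
#' @param grid a [wavenumber_grid()].
#' @return An [ir_spectrum()].
#' @export
atmospheric_reference <- function(grid = wavenumber_grid()) {
  nu <- grid$values
  r <- 1.0 * exp(-((nu - 2360)^2) / (2 * 8^2)) +
       0.8 * exp(-((nu - 2338)^2) / (2 * 8^2))
  centers <- seq(1408, 1792, by = 24)
  amps <- 0.25 + 0.35 * abs(sin(seq_along(centers) * 2.3))
  for (i in seq_along(centers)) {
    r <- r + amps[i] * exp(-((nu - centers[i])^2) / (2 * 7^2))
  }
  ir_spectrum(grid, r / max(r))
}

# Concave-up random scattering baseline, scaled by baseline_scale.
random_baseline <- function(nu, scale) {
  if (scale <= 0) return(numeric(length(nu)))
  u <- (nu - nu[1]) / (nu[length(nu)] - nu[1])
  c0 <- stats::runif(1, 0.1, 0.5)
  c2 <- stats::runif(1, 0.5, 2.0)
  u0 <- stats::runif(1, 0.2, 0.8)
  scale * (c0 + c2 * (u - u0)^2)
}

#' Simulate one MID-IR absorbance spectrum
#'
#' Noise-free expectation is the Gaussian band sum under the saturation law
#' of [band_model()]; on top of that a random concave-up scattering
#' baseline, a random multiple of the atmospheric reference, and white
#' noise are added. Uses (and advances) the current RNG state.
#'
#' @param t fixation time in hours, non-negative.
#' @param bands non-empty list of [band_model()] objects.
#' @param config a [study_config()] (grid and noise scales are used).
#' @return An [ir_spectrum()].
#' @export
#' @examples
#' cfg <- study_config(noise_sd = 0, baseline_scale = 0, atmospheric_scale = 0)
#' s <- simulate_spectrum(4, default_band_set(), cfg)
simulate_spectrum <- function(t, bands = default_band_set(),
                              config = study_config()) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("fixation time t must be a single non-negative number")
  }
  if (!is.list(bands) || length(bands) == 0L) {
    stop("bands must be a non-empty list of band models")
  }
  nu <- config$grid$values
  a <- band_sum(nu, t, bands)
  a <- a + random_baseline(nu, config$baseline_scale)
  if (config$atmospheric_scale > 0) {
    gam <- stats::runif(1, 0.5, 1.5)
    a <- a + config$atmospheric_scale * gam *
      atmospheric_reference(config$grid)$absorbance
  }
  if (config$noise_sd > 0) {
    a <- a + stats::rnorm(length(nu), sd = config$noise_sd)
  }
  ir_spectrum(config$grid, a)
}

# Apply per-tissue lognormal random effects to a band set.
jitter_bands <- function(bands, tau_sd, amp_sd) {
  lapply(bands, function(b) {
    if (tau_sd > 0) b$tau <- b$tau * exp(stats::rnorm(1, sd = tau_sd))
    if (amp_sd > 0) b$amp0 <- b$amp0 * exp(stats::rnorm(1, sd = amp_sd))
    b
  })
}

#' Simulate a full differential-fixation study
#'
#' Generates `length(fixation_times) * tissues_per_time *
#' replicates_per_tissue` slide-level [tissue_record()]s, each carrying
#' `regions_per_slide` point spectra. Tissue-level random effects (band tau
#' and amplitude jitter) are shared by both cuts of a block, as they would
#' be in a real paraffin block; IHC percent positivity per marker is drawn
#' around [ihc_positivity_curve()]. Bit-reproducible from `config$seed`.
#'
#' @param config a [study_config()].
#' @param bands band set; default [default_band_set()].
#' @param ihc_markers markers to attach positivity values for; `NULL` for
#'   none.
#' @param ihc_sd slide-level positivity noise, percentage points.
#' @return list of [tissue_record()]s.
#' @export
simulate_study <- function(config = study_config(),
                           bands = default_band_set(),
                           ihc_markers = c("bcl2", "ki67", "foxp3"),
                           ihc_sd = 2.5) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  records <- vector("list", length(config$fixation_times) *
                      config$tissues_per_time * config$replicates_per_tissue)
  k <- 0L
  tissue_no <- 0L
  for (t in config$fixation_times) {
    for (i in seq_len(config$tissues_per_time)) {
      tissue_no <- tissue_no + 1L
      tb <- jitter_bands(bands, config$tau_jitter_sd, config$amp_jitter_sd)
      ihc <- NULL
      if (!is.null(ihc_markers)) {
        ihc <- vapply(ihc_markers, function(m) {
          p <- ihc_positivity_curve(m, t) + stats::rnorm(1, sd = ihc_sd)
          min(100, max(0, p))
        }, numeric(1))
      }
      for (r in seq_len(config$replicates_per_tissue)) {
        mat <- matrix(0, config$regions_per_slide, length(config$grid$values))
        for (s in seq_len(config$regions_per_slide)) {
          mat[s, ] <- simulate_spectrum(t, tb, config)$absorbance
        }
        k <- k + 1L
        records[[k]] <- tissue_record(
          tissue_id = sprintf("T%03d", tissue_no),
          replicate_id = sprintf("R%d", r),
          fixation_time = t, spectra = mat, grid = config$grid, ihc = ihc)
      }
    }
  }
  records
}
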