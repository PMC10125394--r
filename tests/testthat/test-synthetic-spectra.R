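test_that("wavenumber grid honours its invariants", {
  g <- wavenumber_grid()
  expect_equal(g$values[1], 900)
  expect_equal(length(g$values), 388)
  expect_equal(max(g$values), 3996)          # last point below stop
  expect_true(all(abs(diff(g$values) - 8) < 1e-12))
  expect_error(wavenumber_grid(step = 0), "positive")
  expect_error(wavenumber_grid(1000, 900), "exceed")
})

test_that("noise-free spectrum equals the closed-form band sum", {
  cfg <- quiet_config()
  bands <- default_band_set()
  for (t in c(0, 1.7, 4, 24)) {
    s <- simulate_spectrum(t, bands, cfg)
    # closed form written out independently in the test
    nu <- cfg$grid$values
    expected <- numeric(length(nu))
    for (b in bands) {
      f <- 1 - exp(-t / b$tau)
      expected <- expected + b$amp0 * (1 - b$amp_gain * f) *
        exp(-((nu - (b$center0 + b$center_shift * f))^2) /
              (2 * (b$width0 + b$width_gain * f)^2))
    }
    expect_equal(s$absorbance, expected, tolerance = 1e-12)
  }
})

test_that("single-band examples: argmax follows the saturation law", {
  cfg <- quiet_config()
  b0 <- list(band_model("amide_I", 1626, center_shift = 8, width0 = 22,
                        amp0 = 1, tau = 4))
  s0 <- simulate_spectrum(0, b0, cfg)
  expect_equal(cfg$grid$values[which.max(s0$absorbance)], 1628)  # nearest to 1626
  s_inf <- simulate_spectrum(40, b0, cfg)  # t = 10 tau: saturated
  expect_equal(cfg$grid$values[which.max(s_inf$absorbance)], 1636)  # nearest to 1634
  # t = tau: center at 1626 + 8 (1 - e^-1), checked against a Gaussian fit
  s1 <- simulate_spectrum(4, b0, cfg)
  mu_expected <- 1626 + 8 * (1 - exp(-1))
  nu <- cfg$grid$values
  w <- which(s1$absorbance > 0.1)
  mu_fit <- sum(nu[w] * s1$absorbance[w]) / sum(s1$absorbance[w])
  expect_equal(mu_fit, mu_expected, tolerance = 1e-3)
  expect_error(simulate_spectrum(-1, b0, cfg), "non-negative")
  expect_error(simulate_spectrum(1, list(), cfg), "non-empty")
})

test_that("band model rejects invalid parameters", {
  expect_error(band_model("x", 1600, width0 = 0), "width0")
  expect_error(band_model("x", 1600, tau = -1), "tau")
  expect_error(band_model("x", 1600, amp0 = 0), "amp0")
})

test_that("study geometry, record shape and determinism", {
  cfg <- quiet_config(tissues_per_time = 2, regions_per_slide = 3)
  recs <- simulate_study(cfg, ihc_markers = NULL)
  expect_length(recs, 7 * 2 * 2)
  expect_true(all(vapply(recs, function(r) nrow(r$spectra), integer(1)) == 3))

  single <- study_config(fixation_times = 2, tissues_per_time = 1,
                         replicates_per_tissue = 1, regions_per_slide = 3)
  r1 <- simulate_study(single, ihc_markers = NULL)
  expect_length(r1, 1)
  expect_equal(nrow(r1[[1]]$spectra), 3)

  noisy <- study_config(tissues_per_time = 1, regions_per_slide = 2,
                        seed = 42)
  a <- simulate_study(noisy)
  b <- simulate_study(noisy)
  expect_identical(
    lapply(a, function(r) r$spectra),
    lapply(b, function(r) r$spectra))
  expect_identical(lapply(a, `[[`, "ihc"), lapply(b, `[[`, "ihc"))
})

test_that("study config validation", {
  expect_error(study_config(fixation_times = c(2, 1)), "increasing")
  expect_error(study_config(fixation_times = c(-1, 2)), "non-negative")
  expect_error(study_config(tissues_per_time = 0), "at least 1")
  expect_error(study_config(noise_sd = -0.1), "non-negative")
})

test_that("replicates of a block share tissue-level effects, not noise", {
  cfg <- study_config(fixation_times = 6, tissues_per_time = 1,
                      regions_per_slide = 2, noise_sd = 0,
                      baseline_scale = 0, atmospheric_scale = 0, seed = 7)
  recs <- simulate_study(cfg, ihc_markers = NULL)
  # same tissue, both replicates: identical noise-free spectra
  expect_equal(recs[[1]]$spectra, recs[[2]]$spectra, tolerance = 1e-12)
  # two different tissues differ through the random effects
  cfg2 <- cfg; cfg2$tissues_per_time <- 2L
  recs2 <- simulate_study(cfg2, ihc_markers = NULL)
  expect_gt(max(abs(recs2[[1]]$spectra - recs2[[3]]$spectra)), 1e-6)
})

test_that("mean Amide I derivative peak rises from 0 h to 24 h over tissues", {
  cfg <- study_config(fixation_times = c(0, 24), tissues_per_time = 25,
                      replicates_per_tissue = 1, regions_per_slide = 2,
                      noise_sd = 0, baseline_scale = 0,
                      atmospheric_scale = 0, seed = 11)
  recs <- simulate_study(cfg, ihc_markers = NULL)
  peaks <- vapply(recs, function(r) {
    extract_features(preprocess_tissue(r))$amide1_peak_location
  }, numeric(1))
  t <- vapply(recs, function(r) r$fixation_time, numeric(1))
  expect_gt(mean(peaks[t == 24]), mean(peaks[t == 0]))
})
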