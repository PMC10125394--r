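g <- std_grid()

test_that("absorbance computation follows the decadic Beer-Lambert form", {
  i0 <- ir_spectrum(g, rep(0.8, 388))
  expect_equal(compute_absorbance(i0, i0)$absorbance, rep(0, 388))
  i <- ir_spectrum(g, 0.8 * rep(0.5, 388))
  expect_equal(compute_absorbance(i, i0)$absorbance,
               rep(0.30103, 388), tolerance = 1e-5)
  one_decade <- ir_spectrum(g, replace(rep(0.8, 388), 50, 0.08))
  a <- compute_absorbance(one_decade, i0)
  expect_equal(a$absorbance[50], 1)
  bad_bg <- ir_spectrum(g, replace(rep(1, 388), 10, 0))
  # error names the offending wavenumber (10th point = 972 cm^-1)
  expect_error(compute_absorbance(i0, bad_bg), "972")
})

test_that("atmospheric correction recovers the reference loading", {
  ref <- atmospheric_reference(g)
  s <- ir_spectrum(g, 0.7 * ref$absorbance)
  out <- atmospheric_correction(s, ref)
  expect_equal(attr(out, "alpha"), 0.7, tolerance = 1e-9)
  expect_equal(out$absorbance, rep(0, 388), tolerance = 1e-9)

  zero_ref <- ir_spectrum(g, rep(0, 388))
  s2 <- gaussian_spectrum(1630, 22)
  expect_equal(atmospheric_correction(s2, zero_ref)$absorbance,
               s2$absorbance)

  # a band far outside both fitting windows is untouched (alpha = 0)
  s3 <- gaussian_spectrum(2000, 15)
  out3 <- atmospheric_correction(s3, ref)
  expect_equal(attr(out3, "alpha"), 0, tolerance = 1e-6)
  expect_equal(out3$absorbance, s3$absorbance, tolerance = 1e-6)

  # outside the windows the change is exactly -alpha * reference
  s4 <- ir_spectrum(g, gaussian_spectrum(1630, 22)$absorbance +
                      0.3 * ref$absorbance)
  out4 <- atmospheric_correction(s4, ref)
  a4 <- attr(out4, "alpha")
  expect_equal(out4$absorbance, s4$absorbance - a4 * ref$absorbance)
})

test_that("rubberband: flat and linear inputs correct to zero", {
  line <- ir_spectrum(g, 0.4 + 2e-4 * g$values)
  rb <- rubberband_baseline(line)
  expect_equal(rb$corrected$absorbance, rep(0, 388), tolerance = 1e-9)
  zero <- ir_spectrum(g, rep(0, 388))
  rbz <- rubberband_baseline(zero)
  expect_equal(rbz$baseline$absorbance, rep(0, 388))
  expect_equal(rbz$corrected$absorbance, rep(0, 388))
  short <- ir_spectrum(wavenumber_grid(900, 1100, 8), rep(1, 26))
  expect_error(rubberband_baseline(short), "64 baseline points")
})

test_that("rubberband agrees with the two-point line oracle on a linear
           baseline and preserves an isolated peak", {
  nu <- g$values
  line <- 0.2 + 1.5e-4 * nu
  peak <- exp(-((nu - 1630)^2) / (2 * 22^2))
  sp <- ir_spectrum(g, line + peak)
  rb <- rubberband_baseline(sp)
  # oracle: straight line through the two end points
  oracle <- line[1] + (line[388] - line[1]) * (nu - nu[1]) / (nu[388] - nu[1])
  expect_equal(rb$baseline$absorbance, oracle, tolerance = 1e-6)
  # peak height preserved within 2%
  i <- which.min(abs(nu - 1630))
  expect_lt(abs(rb$corrected$absorbance[i] - peak[i]), 0.02)
})

test_that("rubberband contract at support points and fixed point", {
  set.seed(4)
  nu <- g$values
  vals <- 0.3 + 0.5 * ((nu - 2000) / 3100)^2 +
    0.8 * exp(-((nu - 1650)^2) / (2 * 30^2)) +
    0.4 * exp(-((nu - 3290)^2) / (2 * 60^2)) +
    rnorm(388, sd = 0.005)
  sp <- ir_spectrum(g, vals)
  rb <- rubberband_baseline(sp)
  sup <- rb$support
  expect_true(all(rb$baseline$absorbance[sup] <= vals[sup] + 1e-9))
  expect_true(all(rb$corrected$absorbance[sup] >= -1e-9))
  # re-applying to the corrected signal changes little
  rb2 <- rubberband_baseline(rb$corrected)
  expect_lt(max(abs(rb2$baseline$absorbance)), 0.02 * max(vals))
})

test_that("normalization contract", {
  s <- gaussian_spectrum(1630, 22, amp = 2.5, offset = 0.1)
  n1 <- normalize_amplitude(s)
  expect_equal(max(n1$absorbance), 1)
  expect_equal(n1$absorbance, s$absorbance / max(s$absorbance))
  expect_equal(normalize_amplitude(n1)$absorbance, n1$absorbance)
  s3 <- ir_spectrum(g, 3 * s$absorbance)
  expect_equal(normalize_amplitude(s3)$absorbance, n1$absorbance)
  expect_error(normalize_amplitude(ir_spectrum(g, rep(0, 388))),
               "not positive")
  expect_error(normalize_amplitude(ir_spectrum(g, rep(-1, 388))),
               "not positive")
})

test_that("averaging is a pointwise mean on a common grid", {
  a <- ir_spectrum(g, rep(0, 388))
  b <- ir_spectrum(g, rep(2, 388))
  expect_equal(average_spectra(list(a, b))$absorbance, rep(1, 388))
  expect_equal(average_spectra(list(b))$absorbance, b$absorbance)
  expect_equal(average_spectra(list(b, b, b))$absorbance, b$absorbance)
  other <- ir_spectrum(wavenumber_grid(900, 2000, 8), rep(1, 138))
  expect_error(average_spectra(list(a, other)), "different grids")
  expect_error(average_spectra(list()), "non-empty")
})

test_that("tissue pipeline composes the stages in the documented order", {
  cfg <- quiet_config(fixation_times = 4, tissues_per_time = 1,
                      replicates_per_tissue = 1, regions_per_slide = 3)
  rec <- simulate_study(cfg, ihc_markers = NULL)[[1]]
  out <- preprocess_tissue(rec)
  # noise-free record of identical spectra: equals the single-spectrum chain
  single <- ir_spectrum(g, rec$spectra[1, ])
  chain <- normalize_amplitude(
    rubberband_baseline(atmospheric_correction(single))$corrected)
  expect_equal(out$absorbance, chain$absorbance, tolerance = 1e-10)
  # and approximates the normalized band sum (rubber band only nibbles tails)
  bs <- rec$spectra[1, ]
  expect_equal(out$absorbance, bs / max(bs), tolerance = 0.02)
  # permutation invariance of the spatial average
  rec2 <- rec
  rec2$spectra <- rec$spectra[c(3, 1, 2), ]
  expect_equal(preprocess_tissue(rec2)$absorbance, out$absorbance)
})

test_that("full chain is invariant to positive rescaling of the input", {
  set.seed(8)
  cfg <- study_config(fixation_times = 6, tissues_per_time = 1,
                      replicates_per_tissue = 1, regions_per_slide = 2,
                      seed = 13)
  rec <- simulate_study(cfg, ihc_markers = NULL)[[1]]
  scaled <- rec
  scaled$spectra <- 3.7 * rec$spectra
  expect_equal(preprocess_tissue(scaled)$absorbance,
               preprocess_tissue(rec)$absorbance, tolerance = 1e-9)
})
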