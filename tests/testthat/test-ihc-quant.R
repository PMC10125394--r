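test_that("segmentation: blank slides and ground-truth agreement", {
  white <- array(0.98, dim = c(32, 32, 3))
  seg <- segment_tissue(white)
  expect_false(any(seg$active_mask))
  expect_error(segment_tissue(matrix(1, 4, 4)), "RGB")

  sim <- simulate_ihc_image(30, shape = c(128, 128), seed = 11)
  seg <- segment_tissue(sim$image)
  inter <- sum(seg$active_mask & sim$active_mask)
  dice <- 2 * inter / (sum(seg$active_mask) + sum(sim$active_mask))
  expect_gte(dice, 0.95)
  expect_false(any(seg$active_mask & seg$excluded_mask))
})

test_that("segmentation keys on luminance, not background hue", {
  sim <- simulate_ihc_image(20, shape = c(96, 96), seed = 13)
  seg1 <- segment_tissue(sim$image)
  inverted <- sim$image
  bg <- !(sim$active_mask | sim$stroma_mask)
  for (ch in 1:3) {
    plane <- inverted[, , ch]
    plane[bg] <- 1 - plane[bg]   # white slide -> near-black slide
    inverted[, , ch] <- plane
  }
  seg2 <- segment_tissue(inverted)
  changed <- mean(seg1$active_mask != seg2$active_mask)
  expect_lt(changed, 0.01)
})

test_that("positivity classification recovers the ground truth", {
  sim <- simulate_ihc_image(30, shape = c(128, 128), seed = 17)
  seg <- segment_tissue(sim$image)
  pos <- classify_positive(sim$image, seg$active_mask)
  seg$positive_mask <- pos
  expect_lt(abs(percent_positivity(seg) - 30), 2)

  # no DAB at all -> zero percent
  sim0 <- simulate_ihc_image(0, shape = c(96, 96), seed = 19)
  seg0 <- segment_tissue(sim0$image)
  seg0$positive_mask <- classify_positive(sim0$image, seg0$active_mask)
  expect_equal(percent_positivity(seg0), 0, tolerance = 0.5)

  # optical density is ratio-based: a brightness change barely moves it
  brighter <- sim$image * 1.5
  brighter[brighter > 1] <- 1
  segb <- segment_tissue(sim$image)  # same geometry
  posb <- classify_positive(brighter, segb$active_mask)
  segb$positive_mask <- posb
  expect_lt(abs(percent_positivity(segb) - percent_positivity(seg)), 2)

  expect_warning(
    classify_positive(sim$image, matrix(FALSE, 128, 128)), "empty")
})

test_that("percent positivity is plain arithmetic on the masks", {
  act <- matrix(FALSE, 20, 20); act[1:10, ] <- TRUE      # 200 px
  pos <- matrix(FALSE, 20, 20); pos[1:10, 1:5] <- TRUE   # 50 px
  seg <- structure(list(active_mask = act, excluded_mask = !act,
                        positive_mask = pos),
                   class = "segmentation_result")
  expect_equal(percent_positivity(seg), 25)
  seg$positive_mask <- act
  expect_equal(percent_positivity(seg), 100)
  seg$positive_mask <- matrix(FALSE, 20, 20)
  expect_equal(percent_positivity(seg), 0)
  seg$active_mask <- matrix(FALSE, 20, 20)
  expect_error(percent_positivity(seg), "empty")
})

test_that("hot-spot maps localize expression density", {
  act <- matrix(TRUE, 40, 40)
  pos <- matrix(FALSE, 40, 40)
  seg <- structure(list(active_mask = act, excluded_mask = !act,
                        positive_mask = pos),
                   class = "segmentation_result")
  expect_true(all(hotspot_map(seg, 5) == 0, na.rm = TRUE))
  # uniform positivity -> constant map
  seg$positive_mask <- act
  h <- hotspot_map(seg, 5)
  expect_equal(range(h, na.rm = TRUE), c(1, 1))
  # a single cluster peaks at its centroid
  seg$positive_mask <- matrix(FALSE, 40, 40)
  seg$positive_mask[18:22, 18:22] <- TRUE
  h <- hotspot_map(seg, 6)
  peak <- which(h == max(h, na.rm = TRUE), arr.ind = TRUE)
  expect_true(all(abs(peak[, 1] - 20) <= 6 & abs(peak[, 2] - 20) <= 6))
  expect_error(hotspot_map(seg, 0), "at least 1")
})

test_that("normalization to the 24 h group", {
  rec <- data.frame(fixation_time = rep(c(0, 6, 24), each = 2),
                    percent_positive = c(10, 10, 20, 20, 40, 40))
  out <- normalize_to_max(rec)
  expect_equal(out$normalized, c(0.25, 0.5, 1))
  same <- data.frame(fixation_time = c(0, 24), percent_positive = c(7, 7))
  expect_equal(normalize_to_max(same)$normalized, c(1, 1))
  only24 <- data.frame(fixation_time = 24, percent_positive = 9)
  expect_equal(normalize_to_max(only24)$normalized, 1)
  no24 <- data.frame(fixation_time = c(0, 6), percent_positive = c(1, 2))
  expect_error(normalize_to_max(no24), "24 h")
})

test_that("rank-sum test: exact enumeration and approximation agree", {
  # {1,2,3} vs {4,5,6}: 2 / C(6,3) labelings are as extreme
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(ranksum_test(c(4, 5, 6), c(1, 2, 3)), 0.1)
  expect_equal(ranksum_test(c(2, 2, 2), c(2, 2)), 1)
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")

  # independent oracle: stats::wilcox.test exact p on tie-free samples
  set.seed(41)
  for (i in 1:5) {
    a <- sample(100, 5); b <- sample(200, 6)
    expect_equal(ranksum_test(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12, info = paste("draw", i))
  }
  # exact vs normal approximation within 0.02 at n = m = 6
  set.seed(43)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    expect_lt(abs(ranksum_test(a, b, method = "exact") -
                    ranksum_test(a, b, method = "normal")), 0.02)
  }
  # large-sample path with ties runs and is sane
  p <- ranksum_test(rep(1:5, 3), rep(2:6, 3))
  expect_true(p > 0 && p <= 1)
})
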