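# PLS1 machinery against independent oracles: exact rank-1 recovery,
# ordinary least squares at full rank, and the Krylov-subspace formulation.

make_rank1 <- function(n = 24, p = 6, seed = 2) {
  set.seed(seed)
  x <- matrix(0, n, p)
  x[, 3] <- rnorm(n)
  y <- 2 + 1.5 * x[, 3]
  feature_matrix(x, pmax(y - min(y), 0))  # keep y non-negative
}

test_that("rank-1 problems are recovered exactly with one component", {
  fm <- make_rank1()
  m <- fit_plsr(fm, 1)
  pred <- predict(m, fm)
  expect_equal(pred, fm$y, tolerance = 1e-9)
  cs <- coefficient_spectrum(m)
  expect_equal(which.max(abs(cs$coefficient)), 3)
  expect_gt(cs$coefficient[3], 0)  # positive predictor, positive sign
  # zero-variance columns get exactly zero coefficients
  expect_equal(cs$coefficient[-3], rep(0, 5))
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(5)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- abs(drop(X %*% beta) + 5)
  fm <- feature_matrix(X, y)
  m <- fit_plsr(fm, p)
  # OLS oracle via the normal equations on centered data
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  b_ols <- solve(crossprod(Xc), crossprod(Xc, yc))
  pred_ols <- drop(Xc %*% b_ols) + mean(y)
  expect_equal(predict(m, fm), pred_ols, tolerance = 1e-6)
})

test_that("NIPALS matches the Krylov-subspace oracle on random problems", {
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 15), 20, 15)
    y <- abs(rnorm(20, mean = 3))
    fm <- feature_matrix(X, y)
    newX <- matrix(rnorm(8 * 15), 8, 15)
    for (k in c(1, 3, 5)) {
      m <- fit_plsr(fm, k)
      expect_equal(predict(m, newX), krylov_pls_oracle(X, y, k, newX),
                   tolerance = 1e-6,
                   info = sprintf("seed %d, k %d", seed, k))
    }
  }
})

test_that("scores are orthogonal and the model is row-order invariant", {
  set.seed(7)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- abs(rnorm(25, 2))
  fm <- feature_matrix(X, y)
  m <- fit_plsr(fm, 5)
  # reconstruct scores from weights via the deflation-free rotation
  R <- m$weights %*% solve(crossprod(m$x_loadings, m$weights))
  S <- sweep(X, 2, m$x_mean) %*% R
  gram <- crossprod(S)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8 * max(diag(gram)))

  perm <- sample(25)
  m2 <- fit_plsr(feature_matrix(X[perm, ], y[perm]), 5)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-9)
  expect_error(fit_plsr(feature_matrix(X, rep(3, 25)), 2), "constant")
  expect_error(fit_plsr(fm, 30), "between 1 and")
})

test_that("prediction contract: centering identity and null space", {
  fm <- make_rank1()
  m <- fit_plsr(fm, 1)
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean)
  # adding a vector orthogonal to the coefficients leaves predictions alone
  null_vec <- c(1, 0, 0, 0, 0, 0)  # coefficient support is column 3 only
  x <- fm$x[4, , drop = FALSE]
  expect_equal(predict(m, x + 10 * null_vec), predict(m, x))
  expect_error(predict(m, matrix(0, 1, 4)), "expects")
})

test_that("holdout split reproduces the printed design sizes", {
  # 210 slides: 105 blocks in duplicate across 7 times
  y <- rep(rep(c(0, 1, 2, 4, 6, 12, 24), each = 15), times = 2)
  tissue <- rep(sprintf("T%03d", 1:105), times = 2)
  fm <- feature_matrix(matrix(rnorm(210 * 4), 210, 4), y,
                       row_ids = paste0(tissue, "_", rep(1:2, each = 105)),
                       group_ids = tissue)
  sp <- split_holdout(fm, 0.25, seed = 3)
  expect_equal(length(sp$validation$y), 52)
  expect_equal(length(sp$train$y), 158)
  # disjoint, exhaustive, stratified: every time present in validation
  expect_length(intersect(sp$train$row_ids, sp$validation$row_ids), 0)
  expect_setequal(unique(sp$validation$y), unique(y))
  # replicates stay together
  val_tissues <- sp$validation$group_ids
  expect_true(all(table(val_tissues) == 2))
  # reproducibility
  sp2 <- split_holdout(fm, 0.25, seed = 3)
  expect_identical(sp$validation$row_ids, sp2$validation$row_ids)
})

test_that("small-stratum splits behave as documented", {
  fm <- feature_matrix(matrix(rnorm(16), 4, 4), c(0, 0, 24, 24))
  sp <- split_holdout(fm, 0.5, seed = 1)
  expect_equal(length(sp$validation$y), 2)
  expect_setequal(sp$validation$y, c(0, 24))
  expect_error(split_holdout(fm, 0), "between 0 and 1")
  lone <- feature_matrix(matrix(rnorm(8), 2, 4), c(0, 24))
  expect_error(split_holdout(lone, 0.5), "at least 2")
})

test_that("component selection finds the true latent dimension", {
  set.seed(31)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  load1 <- rnorm(12); load2 <- rnorm(12)
  X <- outer(f1, load1) + outer(f2, load2) + matrix(rnorm(n * 12, sd = 1e-4), n)
  y <- abs(3 + 2 * f1 - f2)
  # y depends on exactly 2 independent latent directions
  sel <- select_components(feature_matrix(X, y), max_components = 8,
                           folds = 2, seed = 31)
  expect_equal(sel$n_components, 2L)
  expect_true(all(diff(sel$diagnostics$cv_mse[1:2]) < 0))

  sel1 <- select_components(feature_matrix(X, y), max_components = 1,
                            folds = 2, seed = 31)
  expect_equal(sel1$n_components, 1L)

  # pure-noise response: the parsimony rule stays at the minimum
  set.seed(77)
  Xn <- matrix(rnorm(40 * 10), 40, 10)
  yn <- abs(rnorm(40, 5))
  seln <- select_components(feature_matrix(Xn, yn), max_components = 6,
                            folds = 2, seed = 77)
  expect_equal(seln$n_components, 1L)
  expect_error(select_components(feature_matrix(Xn, yn), folds = 1), "folds")
})

test_that("evaluation report computes MAE and a proper CDF", {
  ev <- evaluate_predictions(c(1, 4, 2), c(2, 2, 5))
  expect_equal(ev$mae, 2)
  expect_equal(ev$abs_errors, c(1, 2, 3))
  expect_true(all(diff(ev$cdf$abs_error) >= 0))
  expect_true(all(diff(ev$cdf$prob) > 0))
  perfect <- evaluate_predictions(c(1, 2), c(1, 2))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$cdf$abs_error, c(0, 0))
  dup <- evaluate_predictions(rep(c(1, 4, 2), 2), rep(c(2, 2, 5), 2))
  expect_equal(dup$mae, 2)
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "empty")
  expect_error(evaluate_predictions(1:3, 1:2), "lengths differ")
})

test_that("model JSON round-trips to identical predictions", {
  fm <- make_rank1()
  m <- fit_plsr(fm, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path, provenance = list(seed = 2))
  m2 <- read_model_json(path)
  expect_equal(predict(m2, fm), predict(m, fm), tolerance = 1e-12)
  expect_equal(m2$n_components, m$n_components)
})
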