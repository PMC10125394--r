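# Fixation-time prediction by PLS1 regression (NIPALS): stratified holdout
# split, twofold cross-validated component selection, fit, prediction,
# MAE/CDF evaluation and coefficient-spectrum export.

#' Feature matrix for the fixation model
#'
#' Rows are slide-level samples; columns are predictors — by default the
#' full preprocessed spectrum, one column per wavenumber.
#'
#' @param x numeric matrix, no missing values.
#' @param y fixation time per row (hours, non-negative; `NA` allowed for
#'   unknown specimens at prediction time).
#' @param row_ids character row identifiers.
#' @param group_ids optional character vector marking rows that must stay
#'   in the same split partition (e.g. replicate cuts of one block);
#'   default each row is its own group.
#' @param wavenumber optional predictor axis (cm^-1), for coefficient
#'   export.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, y, row_ids = NULL, group_ids = NULL,
                           wavenumber = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix must have no missing values")
  if (length(y) != nrow(x)) stop("y must have one value per row")
  if (any(y < 0, na.rm = TRUE)) stop("fixation times must be non-negative")
  if (is.null(row_ids)) row_ids <- sprintf("row%04d", seq_len(nrow(x)))
  if (is.null(group_ids)) group_ids <- row_ids
  if (!is.null(wavenumber) && length(wavenumber) != ncol(x)) {
    stop("wavenumber must have one value per column")
  }
  structure(list(x = x, y = as.numeric(y), row_ids = as.character(row_ids),
                 group_ids = as.character(group_ids),
                 wavenumber = wavenumber),
            class = "feature_matrix")
}

#' Build the feature matrix of a study from its tissue records
#'
#' Preprocesses every record ([preprocess_tissue()]) and stacks the
#' representative spectra as predictor rows; replicate cuts of a block
#' share a `group_id` so splits can keep them together.
#'
#' @param records list of [tissue_record()]s.
#' @param config a [preprocess_config()].
#' @return a [feature_matrix()].
#' @export
build_feature_matrix <- function(records, config = preprocess_config()) {
  if (length(records) == 0L) stop("no records")
  grid <- records[[1]]$grid
  x <- matrix(0, length(records), length(grid$values))
  for (i in seq_along(records)) {
    x[i, ] <- preprocess_tissue(records[[i]], config)$absorbance
  }
  feature_matrix(
    x,
    y = vapply(records, function(r) r$fixation_time, numeric(1)),
    row_ids = vapply(records, function(r)
      paste(r$tissue_id, r$replicate_id, sep = "/"), character(1)),
    group_ids = vapply(records, function(r) r$tissue_id, character(1)),
    wavenumber = grid$values)
}

subset_fm <- function(fm, rows) {
  feature_matrix(fm$x[rows, , drop = FALSE], fm$y[rows], fm$row_ids[rows],
                 fm$group_ids[rows], fm$wavenumber)
}

# Largest-remainder allocation of `total` units across strata with sizes
# `sizes` at fraction `frac`; ties among remainders broken by a seeded draw.
allocate_stratified <- function(sizes, frac, total) {
  quota <- frac * sizes
  base <- floor(quota)
  extra <- total - sum(base)
  if (extra > 0) {
    rem <- quota - base
    ord <- order(rem, stats::runif(length(rem)), decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  pmin(base, sizes)
}

#' Stratified holdout split
#'
#' Splits the samples into training and validation sets, stratified by
#' fixation time. The split operates on replicate groups (`group_ids`), so
#' both cuts of a block land on the same side; the total validation size is
#' `floor(holdout_frac * n_groups)` groups, allocated across strata by
#' per-stratum floor plus largest-remainder. A stratum whose group
#' structure cannot support a split (fewer than 2 groups) falls back to
#' slide-level splitting within that stratum. With the printed design
#' (105 blocks in duplicate, 25%) this reproduces 52 validation and 158
#' training slides.
#'
#' @param fm a [feature_matrix()] with known `y`.
#' @param holdout_frac fraction in (0, 1).
#' @param seed integer seed; the same seed reproduces the partition.
#' @return list with `train` and `validation` [feature_matrix()]s.
#' @export
split_holdout <- function(fm, holdout_frac = 0.25, seed = 1L) {
  if (holdout_frac <= 0 || holdout_frac >= 1) {
    stop("holdout_frac must be strictly between 0 and 1")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  strata <- split(seq_along(fm$y), fm$y)
  # unit = replicate group where possible, else slide
  units <- lapply(strata, function(rows) {
    g <- split(rows, fm$group_ids[rows])
    if (length(g) >= 2) g else as.list(rows)
  })
  sizes <- vapply(units, length, integer(1))
  if (any(sizes < 2)) {
    stop("every fixation-time stratum needs at least 2 units to split")
  }
  total <- floor(holdout_frac * sum(sizes))
  if (total < 1) stop("holdout fraction too small: empty validation set")
  n_val <- allocate_stratified(sizes, holdout_frac, total)
  val_rows <- integer(0)
  for (s in seq_along(units)) {
    pick <- sample.int(sizes[s], n_val[s])
    val_rows <- c(val_rows, unlist(units[[s]][pick]))
  }
  val_rows <- sort(val_rows)
  train_rows <- setdiff(seq_along(fm$y), val_rows)
  list(train = subset_fm(fm, train_rows),
       validation = subset_fm(fm, val_rows))
}

# Core NIPALS PLS1 iteration on centered data. Stops early (without
# erroring) when the residual covariance vanishes, i.e. the rank is
# exhausted; returns the achieved component count.
nipals_components <- function(Xc, yc, kmax) {
  pcol <- ncol(Xc)
  W <- matrix(0, pcol, kmax)
  P <- matrix(0, pcol, kmax)
  Q <- numeric(kmax)
  ss_vec <- numeric(kmax)
  scale0 <- sqrt(sum(crossprod(Xc, yc)^2)) + 1e-300
  achieved <- 0L
  for (k in seq_len(kmax)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10 * scale0 || sum(Xc^2) < 1e-24) break
    w <- w / nw
    s <- drop(Xc %*% w)
    ss <- sum(s^2)
    p <- drop(crossprod(Xc, s)) / ss
    q <- sum(yc * s) / ss
    Xc <- Xc - tcrossprod(s, p)
    yc <- yc - q * s
    W[, k] <- w; P[, k] <- p; Q[k] <- q; ss_vec[k] <- ss
    achieved <- k
  }
  idx <- seq_len(max(achieved, 1L))
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Q = Q[idx], ss = ss_vec[idx], achieved = achieved)
}

#' Fit a PLS1 regression by NIPALS
#'
#' Centers `X` and `y` (no variance scaling: spectra arrive
#' amplitude-normalized); then per component takes the weight
#' `w = X'y / ||X'y||`, scores `s = Xw`, loadings `p = X's/(s's)`,
#' `q = y's/(s's)`, and deflates `X <- X - s p'`, `y <- y - q s`.
#' Regression coefficients are assembled as `W (P'W)^{-1} q` so that
#' `yhat = y_mean + (x - x_mean)' b`.
#'
#' @param train a [feature_matrix()].
#' @param n_components number of latent components, within rank bounds.
#' @return Object of class `plsr_model`: `x_mean`, `y_mean`, `weights`,
#'   `x_loadings`, `y_loadings`, `coefficients`, `n_components`,
#'   `variance_explained` (list with per-component fractions for X and y),
#'   `wavenumber`.
#' @export
fit_plsr <- function(train, n_components) {
  X <- train$x
  y <- train$y
  n <- nrow(X); pcol <- ncol(X)
  if (n_components < 1 || n_components > min(n - 1, pcol)) {
    stop("n_components must be between 1 and min(rows - 1, columns)")
  }
  if (stats::var(y) == 0) stop("constant fixation times: nothing to regress")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  ssx_tot <- sum(Xc^2)
  ssy_tot <- sum(yc^2)

  nip <- nipals_components(Xc, yc, n_components)
  if (nip$achieved < n_components) {
    stop(sprintf("component %d exceeds the rank of the training data",
                 nip$achieved + 1L))
  }
  W <- nip$W; P <- nip$P; Q <- nip$Q
  varx <- nip$ss * colSums(P^2) / ssx_tot
  vary <- Q^2 * nip$ss / ssy_tot
  R <- W %*% solve(crossprod(P, W))
  coefficients <- drop(R %*% Q)
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W,
                 x_loadings = P, y_loadings = Q,
                 coefficients = coefficients,
                 n_components = as.integer(n_components),
                 variance_explained = list(x = varx, y = vary),
                 wavenumber = train$wavenumber),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf(
    "<plsr_model> %d components, %d predictors; y variance explained %.1f%%\n",
    x$n_components, length(x$coefficients),
    100 * sum(x$variance_explained$y)))
  invisible(x)
}

#' Predict fixation times
#'
#' `yhat = y_mean + (x - x_mean)' b` per row; predictions are not clipped,
#' so values below 0 (or above the design range) are reported as-is — they
#' are diagnostic signal.
#'
#' @param object a fitted [fit_plsr()] model.
#' @param newdata a [feature_matrix()] or bare numeric matrix with matching
#'   columns.
#' @param ... unused.
#' @return numeric vector of predicted hours.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_matrix")) newdata$x else
    as.matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(X), length(object$coefficients)))
  }
  drop(sweep(X, 2, object$x_mean) %*% object$coefficients) + object$y_mean
}

# Stratified k-fold assignment over rows, seeded: rows are ordered by y
# (random tie-break) and folds assigned cyclically, so each fold sees the
# full response range whether y is discrete or continuous.
stratified_folds <- function(y, folds, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  ord <- order(y, stats::runif(length(y)))
  fold <- integer(length(y))
  fold[ord] <- rep_len(sample(seq_len(folds)), length(y))
  fold
}

#' Choose the component count by twofold cross-validation
#'
#' For `k = 1..max_components` computes the stratified `folds`-fold
#' cross-validated mean squared prediction error — averaged over
#' `cv_repeats` independent fold assignments to damp the variance of a
#' single twofold split — and the per-component variance explained, then
#' returns the smallest `k` whose CV-MSE is within 5% of the global
#' minimum (one-sided parsimony rule).
#'
#' @param train a [feature_matrix()].
#' @param max_components largest count to try.
#' @param folds number of folds, at least 2 (default 2).
#' @param seed fold-assignment seed.
#' @param tol_frac parsimony tolerance (default 0.05).
#' @param cv_repeats independent fold assignments to average (default 5).
#' @return list with `n_components` and a `diagnostics` data.frame
#'   (`k`, `cv_mse`, `var_x`, `var_y`).
#' @export
select_components <- function(train, max_components = 15, folds = 2,
                              seed = 1L, tol_frac = 0.05, cv_repeats = 5) {
  if (folds < 2) stop("folds must be at least 2")
  if (max_components < 1) stop("max_components must be at least 1")
  max_k <- min(max_components,
               floor(nrow(train$x) * (folds - 1) / folds) - 1,
               ncol(train$x))
  sse <- numeric(max_k)
  achieved_min <- max_k
  for (rep in seq_len(cv_repeats)) {
    fold <- stratified_folds(train$y, folds, seed + (rep - 1L) * 7919L)
    for (f in seq_len(folds)) {
      tr <- subset_fm(train, which(fold != f))
      te <- subset_fm(train, which(fold == f))
      x_mean <- colMeans(tr$x)
      y_mean <- mean(tr$y)
      nip <- nipals_components(sweep(tr$x, 2, x_mean), tr$y - y_mean, max_k)
      if (nip$achieved == 0) {  # degenerate fold: mean-only prediction
        sse <- sse + sum((y_mean - te$y)^2)
        next
      }
      achieved_min <- min(achieved_min, nip$achieved)
      # predictions for truncated component counts, reusing one fit
      R <- nip$W %*% solve(crossprod(nip$P, nip$W))
      Xc <- sweep(te$x, 2, x_mean)
      for (k in seq_len(nip$achieved)) {
        bk <- drop(R[, seq_len(k), drop = FALSE] %*% nip$Q[seq_len(k)])
        pred <- drop(Xc %*% bk) + y_mean
        sse[k] <- sse[k] + sum((pred - te$y)^2)
      }
      if (nip$achieved < max_k) {  # rank exhausted: carry last error forward
        sse[(nip$achieved + 1):max_k] <- sse[(nip$achieved + 1):max_k] +
          sum((drop(Xc %*% drop(R %*% nip$Q)) + y_mean - te$y)^2)
      }
    }
  }
  max_k_eff <- achieved_min
  cv_mse <- (sse / (nrow(train$x) * cv_repeats))[seq_len(max_k_eff)]
  best <- min(cv_mse)
  n_comp <- which(cv_mse <= best * (1 + tol_frac))[1]
  # rank on the full training set can exceed the per-fold rank
  x_mean <- colMeans(train$x)
  full <- nipals_components(sweep(train$x, 2, x_mean),
                            train$y - mean(train$y), max_k_eff)
  n_comp <- min(n_comp, full$achieved)
  ssx_tot <- sum(sweep(train$x, 2, x_mean)^2)
  ssy_tot <- sum((train$y - mean(train$y))^2)
  list(n_components = as.integer(n_comp),
       diagnostics = data.frame(
         k = seq_len(max_k_eff), cv_mse = cv_mse,
         var_x = (full$ss * colSums(full$P^2) / ssx_tot)[seq_len(max_k_eff)],
         var_y = (full$Q^2 * full$ss / ssy_tot)[seq_len(max_k_eff)]))
}

#' Evaluate predictions against known fixation times
#'
#' @param predictions,truth equal-length numeric vectors (hours).
#' @return Object of class `eval_report`: `predictions`, `truth`,
#'   `abs_errors`, `mae`, `cdf` (data.frame of sorted absolute errors and
#'   cumulative probability), and `by_time` (per-fixation-time error
#'   summary for box plots).
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(predictions) == 0L) stop("empty predictions")
  if (length(predictions) != length(truth)) {
    stop("predictions and truth lengths differ")
  }
  abs_err <- abs(predictions - truth)
  sorted <- sort(abs_err)
  report <- list(predictions = predictions, truth = truth,
                 abs_errors = abs_err, mae = mean(abs_err),
                 cdf = data.frame(abs_error = sorted,
                                  prob = seq_along(sorted) / length(sorted)),
                 by_time = split(abs_err, truth))
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, MAE = %.3f h, median |err| = %.3f h\n",
              length(x$abs_errors), x$mae, stats::median(x$abs_errors)))
  invisible(x)
}

#' Export the coefficient spectrum of a fitted model
#'
#' One row per predictor: positive coefficients mark wavenumbers whose
#' absorbance increases the predicted fixation time.
#'
#' @param model a [fit_plsr()] model.
#' @return data.frame with `wavenumber` (cm^-1, or predictor index when the
#'   model was not trained on spectra) and `coefficient`.
#' @export
coefficient_spectrum <- function(model) {
  if (!inherits(model, "plsr_model")) stop("model must be a plsr_model")
  wn <- model$wavenumber
  if (is.null(wn)) wn <- seq_along(model$coefficients)
  data.frame(wavenumber = wn, coefficient = model$coefficients)
}
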