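#' Sample-grouped k-fold assignment
#'
#' Folds partition samples, not spectra: every block spectrum inherits the
#' fold of its parent sample, so the 10 block spectra of one sample never
#' straddle a fold boundary (leakage guard).
#'
#' @param sample_ids vector of parent-sample ids, one per spectrum.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment, one per spectrum; attribute
#'   `sample_folds` maps unique sample to fold.
#' @export
kfold_by_sample <- function(sample_ids, k = 10L, seed = 1L) {
  ids <- unique(sample_ids)
  n <- length(ids)
  if (k < 2L) stop_nirmeat("kfold_by_sample: k must be >= 2")
  if (k > n) {
    stop_nirmeat(sprintf("kfold_by_sample: k = %d exceeds %d samples", k, n))
  }
  perm <- with_local_seed(seed, sample.int(n))
  fold_of_sample <- integer(n)
  fold_of_sample[perm] <- rep_len(seq_len(k), n)
  folds <- fold_of_sample[match(sample_ids, ids)]
  attr(folds, "sample_folds") <- stats::setNames(fold_of_sample, ids)
  folds
}

#' Pooled out-of-fold cross-validation score
#'
#' Fits `fit_fun(Xtr, ytr)` on each training fold and pools the out-of-fold
#' predictions: accuracy (to maximise) for a factor response, RMSE (to
#' minimise) for a numeric one.
#'
#' @param X feature matrix.
#' @param y factor or numeric response.
#' @param folds integer fold assignment, one per row of `X`.
#' @param fit_fun function `(Xtr, ytr) -> model` with a `predict` method.
#' @return list with `score`, pooled `predictions` and the `metric` name.
#' @export
cv_score <- function(X, y, folds, fit_fun) {
  stopifnot(nrow(X) == length(y), length(folds) == length(y))
  classify <- is.factor(y)
  preds <- if (classify) {
    factor(rep(NA_character_, length(y)), levels = levels(y))
  } else {
    rep(NA_real_, length(y))
  }
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- fit_fun(X[tr, , drop = FALSE], y[tr])
    preds[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  score <- if (classify) {
    mean(preds == y)
  } else {
    sqrt(mean((preds - y)^2))
  }
  list(score = score, predictions = preds,
       metric = if (classify) "accuracy" else "rmse")
}

# Feature standardisation fitted on training data only.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}
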