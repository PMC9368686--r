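#' Train an extreme learning machine
#'
#' Single-hidden-layer feed-forward network whose input weights and hidden
#' biases are random (or externally supplied, e.g. by the sparrow search
#' optimizer) and never updated; only the output weights are computed, as the
#' minimum-norm least-squares solution of `H beta = Y` where
#' `H = sigmoid(X W + b)`. Classification targets are one-hot coded and
#' decoded by argmax.
#'
#' @param X numeric feature matrix (spectra x bands).
#' @param y factor (classification) or numeric vector (regression).
#' @param n_hidden number of hidden neurons (study default 60).
#' @param seed integer seed for the random hidden layer.
#' @param init_range range of the uniform weight/bias initialisation.
#' @param weights optional list `list(W, b)` with `W` of dim
#'   `ncol(X) x n_hidden` and `b` of length `n_hidden`, overriding the random
#'   draw.
#' @param scale standardise features (fitted on `X`)?
#' @return object of class `elm_model` with a [predict()] method.
#' @export
train_elm <- function(X, y, n_hidden = 60L, seed = NULL,
                      init_range = c(-1, 1), weights = NULL, scale = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_nirmeat("train_elm: nrow(X) != length(y)")
  if (n_hidden < 1L) stop_nirmeat("train_elm: n_hidden must be >= 1")
  classify <- is.factor(y)
  scaler <- if (scale) fit_scaler(X) else NULL
  Xs <- if (scale) apply_scaler(scaler, X) else X
  d <- ncol(X)
  if (is.null(weights)) {
    weights <- with_local_seed(seed, {
      list(W = matrix(stats::runif(d * n_hidden, init_range[1],
                                   init_range[2]), d, n_hidden),
           b = stats::runif(n_hidden, init_range[1], init_range[2]))
    })
  } else {
    if (!identical(dim(weights$W), c(d, as.integer(n_hidden))) ||
        length(weights$b) != n_hidden) {
      stop_nirmeat("train_elm: supplied weights do not match the architecture")
    }
  }
  H <- stats::plogis(Xs %*% weights$W +
                       matrix(weights$b, nrow(Xs), n_hidden, byrow = TRUE))
  Y <- if (classify) {
    oh <- matrix(0, length(y), nlevels(y))
    oh[cbind(seq_along(y), as.integer(y))] <- 1
    oh
  } else {
    matrix(y, ncol = 1L)
  }
  # minimum-norm least squares via Moore-Penrose pseudo-inverse
  beta <- MASS::ginv(H) %*% Y
  structure(list(weights = weights, beta = beta, scaler = scaler,
                 classify = classify,
                 levels = if (classify) levels(y) else NULL,
                 n_hidden = as.integer(n_hidden)),
            class = "elm_model")
}

#' @export
predict.elm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$scaler)) X <- apply_scaler(object$scaler, X)
  H <- stats::plogis(X %*% object$weights$W +
                       matrix(object$weights$b, nrow(X), object$n_hidden,
                              byrow = TRUE))
  out <- H %*% object$beta
  if (object$classify) {
    factor(object$levels[max.col(out, ties.method = "first")],
           levels = object$levels)
  } else {
    drop(out)
  }
}
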