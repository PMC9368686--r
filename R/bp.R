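#' Train a three-layer back-propagation network
#'
#' Feed-forward perceptron with one logistic-sigmoid hidden layer and a
#' linear output layer, trained by full-batch gradient descent with momentum
#' and an adaptive learning rate (the traingdx contract): after an epoch
#' whose mean-squared error decreased the rate is multiplied by `lr_up`;
#' an epoch that would increase the error by more than `max_perf_inc` is
#' rejected and the rate multiplied by `lr_down`. Classification uses one-hot
#' targets with argmax decoding.
#'
#' @param X numeric feature matrix.
#' @param y factor (classification) or numeric vector (regression).
#' @param hidden hidden-layer size (study default 20).
#' @param max_epochs epoch budget.
#' @param lr_init initial learning rate.
#' @param momentum momentum coefficient.
#' @param lr_up,lr_down adaptive learning-rate factors.
#' @param max_perf_inc tolerated loss-increase ratio before a step is
#'   rejected.
#' @param init_range uniform range for random weight/threshold
#'   initialisation.
#' @param init_weights optional flattened parameter vector
#'   `c(W1, b1, W2, b2)` (e.g. a sparrow-search position) used instead of a
#'   random initialisation.
#' @param goal stop early when the loss falls below this value.
#' @param seed integer seed.
#' @param scale standardise features (fitted on `X`)?
#' @return object of class `bp_model` with a [predict()] method; fields
#'   `loss_history` and `lr_history` log the trajectory.
#' @export
train_bp <- function(X, y, hidden = 20L, max_epochs = 1000L,
                     lr_init = 0.01, momentum = 0.9,
                     lr_up = 1.05, lr_down = 0.7, max_perf_inc = 1.04,
                     init_range = c(-0.5, 0.5), init_weights = NULL,
                     goal = 1e-8, seed = NULL, scale = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_nirmeat("train_bp: nrow(X) != length(y)")
  if (hidden < 1L) stop_nirmeat("train_bp: hidden must be >= 1")
  classify <- is.factor(y)
  scaler <- if (scale) fit_scaler(X) else NULL
  Xs <- if (scale) apply_scaler(scaler, X) else X
  d <- ncol(X)
  K <- if (classify) nlevels(y) else 1L
  n_par <- d * hidden + hidden + hidden * K + K
  if (is.null(init_weights)) {
    init_weights <- with_local_seed(seed, stats::runif(n_par, init_range[1],
                                                       init_range[2]))
  } else if (length(init_weights) != n_par) {
    stop_nirmeat(sprintf(
      "train_bp: init_weights has length %d, architecture needs %d",
      length(init_weights), n_par))
  }
  th <- unflatten_bp(init_weights, d, hidden, K)
  Y <- if (classify) {
    oh <- matrix(0, length(y), K)
    oh[cbind(seq_along(y), as.integer(y))] <- 1
    oh
  } else {
    matrix(y, ncol = 1L)
  }
  n <- nrow(Xs)
  forward <- function(th) {
    Hl <- stats::plogis(Xs %*% th$W1 + matrix(th$b1, n, hidden, byrow = TRUE))
    list(H = Hl,
         O = Hl %*% th$W2 + matrix(th$b2, n, K, byrow = TRUE))
  }
  loss_of <- function(fw) mean((fw$O - Y)^2)
  lr <- lr_init
  vel <- lapply(th, function(w) w * 0)
  fw <- forward(th)
  loss <- loss_of(fw)
  initial_loss <- loss
  loss_hist <- numeric(0)
  lr_hist <- numeric(0)
  epoch <- 0L
  while (epoch < max_epochs && loss > goal) {
    epoch <- epoch + 1L
    E <- 2 * (fw$O - Y) / (n * K)         # dLoss/dO
    gW2 <- t(fw$H) %*% E
    gb2 <- colSums(E)
    dH <- (E %*% t(th$W2)) * fw$H * (1 - fw$H)
    gW1 <- t(Xs) %*% dH
    gb1 <- colSums(dH)
    grad <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    new_vel <- Map(function(v, g) momentum * v - lr * g, vel, grad)
    new_th <- Map(`+`, th, new_vel)
    new_fw <- forward(new_th)
    new_loss <- loss_of(new_fw)
    if (!is.finite(new_loss)) {
      stop_nirmeat(sprintf("train_bp: training diverged at epoch %d", epoch))
    }
    if (new_loss > loss * max_perf_inc) {
      # reject the step, damp the rate, reset momentum
      lr <- lr * lr_down
      vel <- lapply(vel, function(v) v * 0)
    } else {
      lr <- if (new_loss < loss) lr * lr_up else lr * lr_down
      th <- new_th
      vel <- new_vel
      fw <- new_fw
      loss <- new_loss
    }
    loss_hist[epoch] <- loss
    lr_hist[epoch] <- lr
  }
  structure(list(theta = th, scaler = scaler, classify = classify,
                 levels = if (classify) levels(y) else NULL,
                 hidden = as.integer(hidden), d = d, K = K,
                 loss_history = loss_hist, lr_history = lr_hist,
                 epochs = epoch, final_loss = loss,
                 initial_loss = initial_loss, lr_init = lr_init),
            class = "bp_model")
}

# parameter vector layout: c(W1, b1, W2, b2)
unflatten_bp <- function(v, d, hidden, K) {
  i <- 0L
  take <- function(k) {
    out <- v[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
  list(W1 = matrix(take(d * hidden), d, hidden),
       b1 = take(hidden),
       W2 = matrix(take(hidden * K), hidden, K),
       b2 = take(K))
}

#' Number of trainable parameters of the BP architecture
#' @param d input dimension.
#' @param hidden hidden-layer size.
#' @param K output dimension (number of classes, or 1).
#' @return integer parameter count.
#' @export
bp_param_count <- function(d, hidden, K) {
  as.integer(d * hidden + hidden + hidden * K + K)
}

#' @export
predict.bp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$scaler)) X <- apply_scaler(object$scaler, X)
  H <- stats::plogis(X %*% object$theta$W1 +
                       matrix(object$theta$b1, nrow(X), object$hidden,
                              byrow = TRUE))
  O <- H %*% object$theta$W2 + matrix(object$theta$b2, nrow(X), object$K,
                                      byrow = TRUE)
  if (object$classify) {
    factor(object$levels[max.col(O, ties.method = "first")],
           levels = object$levels)
  } else {
    drop(O)
  }
}
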