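#' Train an RBF-kernel SVM or SVR
#'
#' Thin wrapper around [e1071::svm()] (libsvm) giving the uniform fit/predict
#' contract the optimizer expects: C-classification or epsilon-regression
#' with a radial kernel governed by the penalty `c` and kernel radius `g`.
#' Multiclass classification uses libsvm's one-vs-one scheme.
#'
#' @param X numeric feature matrix.
#' @param y factor (classification) or numeric vector (regression).
#' @param c penalty coefficient, `> 0`.
#' @param g RBF kernel radius parameter, `> 0`.
#' @param epsilon SVR tube width on the mass-fraction scale (regression
#'   only; not searched by the optimizer).
#' @param mode `"classify"` or `"regress"`; defaults from the type of `y`.
#' @return object of class `nirmeat_svm` with a [predict()] method.
#' @export
train_svm <- function(X, y, c = 1, g = 1 / ncol(X), epsilon = 0.01,
                      mode = NULL) {
  X <- as.matrix(X)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0 ||
      !is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0) {
    stop_nirmeat("train_svm: c and g must be single positive numbers")
  }
  mode <- mode %||% if (is.factor(y)) "classify" else "regress"
  fit <- if (mode == "classify") {
    e1071::svm(X, y, type = "C-classification", kernel = "radial",
               cost = c, gamma = g, scale = TRUE)
  } else {
    e1071::svm(X, y, type = "eps-regression", kernel = "radial",
               cost = c, gamma = g, epsilon = epsilon, scale = TRUE)
  }
  structure(list(fit = fit, mode = mode, c = c, g = g, epsilon = epsilon),
            class = "nirmeat_svm")
}

#' @export
predict.nirmeat_svm <- function(object, newdata, ...) {
  stats::predict(object$fit, as.matrix(newdata))
}

#' Grid search for SVM/SVR hyperparameters
#'
#' Exhaustive cross-validated evaluation of every `(c, g)` pair, the study's
#' baseline tuning method. Classification maximises CV accuracy, regression
#' minimises CV RMSE; ties go to the smaller `c`, then the smaller `g`.
#'
#' @param X,y training data.
#' @param c_grid,g_grid candidate values; values outside `bounds` are
#'   clipped into it and deduplicated.
#' @param folds integer fold assignment (e.g. from [kfold_by_sample()]).
#' @param epsilon SVR tube width.
#' @param bounds allowed `(lo, hi)` range for both parameters.
#' @return list with `best_c`, `best_g`, `best_score` and the full CV
#'   `table` (`data.frame` with one row per pair).
#' @export
grid_search_svm <- function(X, y, c_grid = 2^seq(-10, 10, 2),
                            g_grid = 2^seq(-10, 10, 2), folds,
                            epsilon = 0.01, bounds = c(1e-5, 100)) {
  clip <- function(v) sort(unique(pmin(pmax(v, bounds[1]), bounds[2])))
  c_grid <- clip(c_grid)
  g_grid <- clip(g_grid)
  if (!length(c_grid) || !length(g_grid)) {
    stop_nirmeat("grid_search_svm: empty grid")
  }
  classify <- is.factor(y)
  tab <- expand.grid(c = c_grid, g = g_grid, KEEP.OUT.ATTRS = FALSE)
  tab <- tab[order(tab$c, tab$g), ]
  tab$score <- NA_real_
  for (r in seq_len(nrow(tab))) {
    tab$score[r] <- cv_score(X, y, folds, function(Xtr, ytr)
      train_svm(Xtr, ytr, c = tab$c[r], g = tab$g[r],
                epsilon = epsilon))$score
  }
  best <- if (classify) which.max(tab$score) else which.min(tab$score)
  rownames(tab) <- NULL
  list(best_c = tab$c[best], best_g = tab$g[best],
       best_score = tab$score[best],
       metric = if (classify) "accuracy" else "rmse", table = tab)
}

#' Sweep the hidden-layer size of a BP or ELM model
#'
#' Reproduces the study's architecture traversal: BP hidden nodes 5..100 in
#' steps of 5, ELM neurons 10..200 in steps of 10, each size scored by
#' sample-grouped cross-validation with fixed folds and seed. Training
#' failures at a size are recorded and the sweep continues. Ties go to the
#' smaller size.
#'
#' @param kind `"bp"` or `"elm"`.
#' @param X,y training data.
#' @param sizes candidate hidden-layer sizes.
#' @param folds integer fold assignment.
#' @param seed integer seed for the per-size model initialisation.
#' @param ... further arguments passed to [train_bp()] / [train_elm()].
#' @return list with `best_size`, `curve` (`data.frame(size, score)`) and
#'   `failures`.
#' @export
sweep_architecture <- function(kind = c("bp", "elm"), X, y,
                               sizes = NULL, folds, seed = 1L, ...) {
  kind <- match.arg(kind)
  sizes <- sizes %||% if (kind == "bp") seq(5L, 100L, 5L) else
    seq(10L, 200L, 10L)
  if (!length(sizes)) stop_nirmeat("sweep_architecture: empty size range")
  classify <- is.factor(y)
  curve <- data.frame(size = sizes, score = NA_real_)
  failures <- list()
  for (si in seq_along(sizes)) {
    res <- tryCatch({
      fit_fun <- if (kind == "bp") {
        function(Xtr, ytr) train_bp(Xtr, ytr, hidden = sizes[si],
                                    seed = derive_seed(seed, 31L, sizes[si]),
                                    ...)
      } else {
        function(Xtr, ytr) train_elm(Xtr, ytr, n_hidden = sizes[si],
                                     seed = derive_seed(seed, 37L, sizes[si]),
                                     ...)
      }
      cv_score(X, y, folds, fit_fun)$score
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(sizes[si])]] <- conditionMessage(res)
    } else {
      curve$score[si] <- res
    }
  }
  if (all(is.na(curve$score))) {
    stop_nirmeat("sweep_architecture: every size failed")
  }
  best <- if (classify) {
    which(curve$score == max(curve$score, na.rm = TRUE))[1L]
  } else {
    which(curve$score == min(curve$score, na.rm = TRUE))[1L]
  }
  list(best_size = sizes[best], curve = curve, failures = failures)
}
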