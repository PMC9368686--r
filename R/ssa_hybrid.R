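#' Tune a model with the sparrow search algorithm
#'
#' Builds the SSA-BP, SSA-ELM and SSA-SVM/SVR hybrids. The search space is
#' `(c, g)` within (1e-5, 100) for SVM/SVR, and the flattened weights and
#' thresholds within (-5, 5) for BP (initial weights, then short training per
#' fold) and ELM (input weights and hidden biases; output weights are always
#' re-solved in closed form, never searched). Fitness of a position is the
#' sample-grouped k-fold cross-validation score of the model instantiated at
#' that position: classification maximises CV accuracy (minimised as
#' `1 - accuracy`), regression minimises CV RMSE. A fold failure poisons the
#' position with the worst possible fitness instead of aborting the search.
#' The final model is refit on the full calibration set at the best position.
#'
#' @param kind `"svm"`, `"svr"`, `"elm"` or `"bp"`.
#' @param X calibration feature matrix (spectra x bands).
#' @param y factor (classification) or numeric mass fractions (regression).
#' @param sample_ids parent-sample ids for grouped folds (defaults to one
#'   sample per row, i.e. ungrouped).
#' @param folds number of CV folds of the fitness.
#' @param seed master integer seed (drives fold assignment and the SSA).
#' @param ssa an [ssa_config()] without bounds, or `NULL` for the study
#'   defaults (population 20, 100 iterations); bounds are set by `kind`.
#' @param level `"spectrum"` evaluates fitness on all rows; `"sample"`
#'   averages the rows of each sample first (cheaper, one spectrum per
#'   sample) while the final refit always uses all rows.
#' @param n_hidden hidden-layer size for `"elm"`/`"bp"`.
#' @param epsilon SVR tube width.
#' @param bp_fitness_epochs BP training epochs inside a fitness evaluation.
#' @param bp_final_epochs BP training epochs of the final refit.
#' @param ssa_n,ssa_iter convenience overrides of the SSA population size
#'   and iteration count.
#' @return list with the fitted `model`, `best_position`, `best_fitness`,
#'   `history`, `folds` and the `search` result.
#' @export
optimize_model <- function(kind = c("svm", "svr", "elm", "bp"), X, y,
                           sample_ids = NULL, folds = 10L, seed = 1L,
                           ssa = NULL, level = c("spectrum", "sample"),
                           n_hidden = if (kind == "elm") 60L else 20L,
                           epsilon = 0.01,
                           bp_fitness_epochs = 100L, bp_final_epochs = 500L,
                           ssa_n = NULL, ssa_iter = NULL) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  X <- as.matrix(X)
  if (nrow(X) == 0L || nrow(X) != length(y)) {
    stop_nirmeat("optimize_model: X and y sizes disagree or are empty")
  }
  classify <- is.factor(y)
  if (kind == "svm" && !classify) stop_nirmeat("optimize_model: svm needs a factor y")
  if (kind == "svr" && classify) stop_nirmeat("optimize_model: svr needs numeric y")
  sample_ids <- sample_ids %||% as.character(seq_len(nrow(X)))

  # fitness data: optionally one mean spectrum per sample
  if (level == "sample") {
    ids <- unique(sample_ids)
    Xf <- rowsum(X, group = match(sample_ids, ids)) /
      as.vector(table(match(sample_ids, ids)))
    yf <- y[match(ids, sample_ids)]
    sf <- ids
  } else {
    Xf <- X
    yf <- y
    sf <- sample_ids
  }
  fold_assign <- kfold_by_sample(sf, k = folds, seed = derive_seed(seed, 41L))

  d_in <- ncol(X)
  # c and g are searched on a log10 scale: the useful kernel-radius region
  # occupies a vanishing fraction of (1e-5, 100) on the natural scale, and
  # log-scale search is the standard practice for RBF hyperparameters.
  # Positions are exponentiated when a model is instantiated, so every
  # candidate (c, g) still lies inside (1e-5, 100).
  dims_bounds <- switch(kind,
    svm = , svr = list(d = 2L, bounds = log10(c(1e-5, 100))),
    elm = list(d = (d_in + 1L) * n_hidden, bounds = c(-5, 5)),
    bp  = list(d = bp_param_count(d_in, n_hidden,
                                  if (classify) nlevels(y) else 1L),
               bounds = c(-5, 5)))

  fit_at <- function(pos, Xtr, ytr, epochs) {
    switch(kind,
      svm = train_svm(Xtr, ytr, c = 10^pos[1], g = 10^pos[2]),
      svr = train_svm(Xtr, ytr, c = 10^pos[1], g = 10^pos[2],
                      epsilon = epsilon),
      elm = train_elm(Xtr, ytr, n_hidden = n_hidden,
                      weights = list(W = matrix(pos[seq_len(d_in * n_hidden)],
                                                d_in, n_hidden),
                                     b = pos[d_in * n_hidden + seq_len(n_hidden)])),
      bp  = train_bp(Xtr, ytr, hidden = n_hidden, init_weights = pos,
                     max_epochs = epochs))
  }
  worst_loss <- if (classify) 1 else Inf
  objective <- function(pos) {
    res <- tryCatch(
      cv_score(Xf, yf, fold_assign, function(Xtr, ytr)
        fit_at(pos, Xtr, ytr, epochs = bp_fitness_epochs)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$score)) return(worst_loss)
    if (classify) 1 - res$score else res$score
  }

  cfg <- ssa %||% ssa_config(n = ssa_n %||% 20L, iter_max = ssa_iter %||% 100L,
                             bounds = dims_bounds$bounds,
                             seed = derive_seed(seed, 43L), sense = "min")
  if (!is.null(ssa)) {
    cfg$bounds <- matrix(dims_bounds$bounds, 1L, 2L)
    cfg$sense <- "min"
    if (is.null(cfg$seed)) cfg$seed <- derive_seed(seed, 43L)
  }
  if (!is.null(ssa_n)) cfg$n <- as.integer(ssa_n)
  if (!is.null(ssa_iter)) cfg$iter_max <- as.integer(ssa_iter)

  search <- run_ssa(objective, cfg, d = dims_bounds$d)
  model <- fit_at(search$position, X, y, epochs = bp_final_epochs)
  best_position <- if (kind %in% c("svm", "svr")) 10^search$position else
    search$position
  list(model = model, best_position = best_position,
       best_fitness = search$fitness, history = search$history,
       folds = fold_assign, kind = kind, level = level, search = search)
}
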