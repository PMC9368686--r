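#' Generate, preprocess and split a full synthetic experiment
#'
#' Runs the data side of the pipeline end to end: expand the design, render
#' pixel spectra, average them into block spectra, crop to the analysed
#' wavelength window, split samples 3:1 (stratified by class for
#' classification, by proportion x part for quantification; quantification
#' uses the adulterated mixtures only), then apply the preprocessing pipeline
#' with its state frozen on the calibration set.
#'
#' @param task `"classify"` or `"quantify"`.
#' @param design a [sample_design()].
#' @param model an [endmember_model()].
#' @param noise a [scatter_noise_model()].
#' @param pixels_per_sample pixel spectra rendered per sample.
#' @param seed master integer seed.
#' @param crop analysed wavelength window in nm.
#' @param prep a [preprocess_config()].
#' @return list with `cal` and `pred` (each `X`, `y`, `ids`), the `split`,
#'   the preprocessing `state` and the processed `spectrum_set`s.
#' @export
prepare_experiment_data <- function(task = c("classify", "quantify"),
                                    design = sample_design(),
                                    model = endmember_model(),
                                    noise = scatter_noise_model(),
                                    pixels_per_sample = 100L, seed = 1L,
                                    crop = c(1000, 2445),
                                    prep = preprocess_config()) {
  task <- match.arg(task)
  tab <- generate_design(design)
  if (task == "quantify") {
    des <- attr(tab, "design")
    tab <- tab[tab$class == "MP", , drop = FALSE]
    attr(tab, "design") <- des
  }
  pix <- generate_sample_spectra(tab, model, noise,
                                 pixels_per_sample = pixels_per_sample,
                                 seed = derive_seed(seed, 61L))
  blocks <- block_mean_spectra(pix, k = design$blocks_per_sample,
                               seed = derive_seed(seed, 67L))
  blocks <- crop_wavelengths(blocks, crop[1], crop[2])
  split <- split_samples(tab, ratio = 0.75,
                         stratify_by = if (task == "classify") "class" else
                           "proportion_part",
                         seed = derive_seed(seed, 71L))
  in_cal <- blocks$meta$sample_id %in% split$calibration
  cal_set <- subset_spectra(blocks, in_cal)
  pred_set <- subset_spectra(blocks, !in_cal)
  cal_p <- preprocess_pipeline(cal_set, prep)
  pred_p <- preprocess_pipeline(pred_set, prep, frozen_state = cal_p$state)
  y_of <- function(s) {
    if (task == "classify") {
      factor(s$meta$class, levels = c("M", "P", "MP"))
    } else {
      s$meta$proportion
    }
  }
  list(task = task,
       cal = list(X = cal_p$spectra$spectra, y = y_of(cal_p$spectra),
                  ids = cal_p$spectra$meta$sample_id),
       pred = list(X = pred_p$spectra$spectra, y = y_of(pred_p$spectra),
                   ids = pred_p$spectra$meta$sample_id),
       split = split, state = cal_p$state,
       cal_set = cal_p$spectra, pred_set = pred_p$spectra,
       sample_table = tab, seed = seed)
}

#' Evaluate one fitted learner under the study protocol
#'
#' Calibration-set figures are 10-fold sample-grouped cross-validation
#' results (pooled out-of-fold predictions); prediction-set figures come
#' from the model fitted on the whole calibration set. Metrics are accuracy
#' plus confusion matrix (classification) or R2 and RMSE (quantification).
#'
#' @param fit_fun function `(X, y) -> model` with a `predict` method.
#' @param data output of [prepare_experiment_data()].
#' @param folds number of CV folds.
#' @param fold_seed seed of the fold assignment (share it across models for
#'   paired comparisons).
#' @param calibration_cv compute the cross-validated calibration-set figures?
#'   Skipping them (`FALSE`) saves the k extra fits when only prediction-set
#'   metrics are needed; the calibration fragment is then `NULL`.
#' @return object of class `eval_report`.
#' @export
evaluate_learner <- function(fit_fun, data, folds = 10L,
                             fold_seed = derive_seed(data$seed, 73L),
                             calibration_cv = TRUE) {
  task <- data$task
  cv <- NULL
  if (calibration_cv) {
    fold_assign <- kfold_by_sample(data$cal$ids, k = folds, seed = fold_seed)
    cv <- cv_score(data$cal$X, data$cal$y, fold_assign, fit_fun)
  }
  model <- fit_fun(data$cal$X, data$cal$y)
  pred <- predict(model, data$pred$X)
  if (task == "classify") {
    cal_frag <- if (calibration_cv)
      confusion_and_accuracy(data$cal$y, cv$predictions)
    pred_frag <- confusion_and_accuracy(data$pred$y, pred)
    predictions <- data.frame(sample_id = data$pred$ids,
                              truth = as.character(data$pred$y),
                              pred = as.character(pred),
                              set = "prediction",
                              stringsAsFactors = FALSE)
  } else {
    cal_frag <- if (calibration_cv)
      regression_metrics(data$cal$y, cv$predictions)
    pred_frag <- regression_metrics(data$pred$y, pred)
    predictions <- data.frame(sample_id = data$pred$ids,
                              truth = data$pred$y, pred = pred,
                              set = "prediction", stringsAsFactors = FALSE)
    if (calibration_cv) {
      predictions <- rbind(
        data.frame(sample_id = data$cal$ids, truth = data$cal$y,
                   pred = cv$predictions, set = "calibration",
                   stringsAsFactors = FALSE), predictions)
    }
  }
  structure(list(task = task, calibration = cal_frag,
                 prediction = pred_frag, predictions = predictions,
                 model = model,
                 protocol = list(task = task, folds = folds,
                                 fold_seed = fold_seed,
                                 calibration_cv = calibration_cv,
                                 split_seed = derive_seed(data$seed, 71L))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "classify") {
    cat(sprintf("<eval_report classify> accuracy: calibration (CV) %s, prediction %.2f%%\n",
                if (is.null(x$calibration)) "-" else
                  sprintf("%.2f%%", 100 * x$calibration$accuracy),
                100 * x$prediction$accuracy))
  } else {
    cat(sprintf("<eval_report quantify> calibration %s | R2p %.4f RMSEP %.4f (g/g)\n",
                if (is.null(x$calibration)) "-" else
                  sprintf("R2c %.4f RMSEC %.4f", x$calibration$r2,
                          x$calibration$rmse),
                x$prediction$r2, x$prediction$rmse))
  }
  invisible(x)
}

#' Run baseline and SSA-optimised models on one synthetic experiment
#'
#' Orchestrates the full comparison for one seed: prepares the data once,
#' evaluates each requested baseline (grid-searched SVM/SVR, fixed-
#' architecture BP and ELM) and its SSA-optimised counterpart under the same
#' split and folds.
#'
#' @param task `"classify"` or `"quantify"`.
#' @param families model families to run: subset of `"svm"` (meaning SVR for
#'   quantification), `"elm"`, `"bp"`.
#' @param optimize also run the SSA hybrids?
#' @param seed master integer seed.
#' @param design,model,noise,pixels_per_sample,prep forwarded to
#'   [prepare_experiment_data()].
#' @param folds CV folds.
#' @param ssa_n,ssa_iter SSA population and iteration budget.
#' @param ssa_level fitness evaluation level, see [optimize_model()]; the
#'   baseline grid search tunes at the same level.
#' @param n_hidden_bp,n_hidden_elm architectures of the network models.
#' @param c_grid,g_grid baseline SVM/SVR search grid.
#' @param bp_epochs training epochs of baseline BP and final SSA-BP refits.
#' @param calibration_cv compute cross-validated calibration metrics (see
#'   [evaluate_learner()])?
#' @param include_baseline evaluate the un-optimised baselines? Skipping them
#'   (with `optimize = TRUE`) runs only the SSA hybrids.
#' @return list with `data`, `baseline` and (optionally) `optimized` lists
#'   of `eval_report`s, and the SSA `searches`.
#' @export
run_experiment <- function(task = c("classify", "quantify"),
                           families = "svm", optimize = TRUE, seed = 1L,
                           design = sample_design(),
                           model = endmember_model(),
                           noise = scatter_noise_model(),
                           pixels_per_sample = 100L,
                           prep = preprocess_config(), folds = 10L,
                           ssa_n = 20L, ssa_iter = 100L,
                           ssa_level = "sample",
                           n_hidden_bp = 20L, n_hidden_elm = 60L,
                           c_grid = 2^seq(-8, 8, 2), g_grid = 2^seq(-8, 8, 2),
                           bp_epochs = 500L, calibration_cv = TRUE,
                           include_baseline = TRUE) {
  task <- match.arg(task)
  data <- prepare_experiment_data(task, design, model, noise,
                                  pixels_per_sample, seed)
  fold_seed <- derive_seed(seed, 73L)
  svm_kind <- if (task == "classify") "svm" else "svr"
  baseline <- list()
  optimized <- list()
  searches <- list()
  # tuning data for the baseline grid search, at the same level as the SSA
  if (identical(ssa_level, "sample")) {
    ids <- unique(data$cal$ids)
    grp <- match(data$cal$ids, ids)
    X_tune <- rowsum(data$cal$X, grp) / as.vector(table(grp))
    y_tune <- data$cal$y[match(ids, data$cal$ids)]
    id_tune <- ids
  } else {
    X_tune <- data$cal$X
    y_tune <- data$cal$y
    id_tune <- data$cal$ids
  }
  for (fam in families) {
    fit_fun <- if (!include_baseline) NULL else switch(fam,
      svm = {
        # baseline tuning: the study's cross-validated grid search
        gs_folds <- kfold_by_sample(id_tune, k = folds, seed = fold_seed)
        gs <- grid_search_svm(X_tune, y_tune, c_grid, g_grid,
                              folds = gs_folds)
        function(Xtr, ytr) train_svm(Xtr, ytr, c = gs$best_c, g = gs$best_g)
      },
      elm = function(Xtr, ytr)
        train_elm(Xtr, ytr, n_hidden = n_hidden_elm,
                  seed = derive_seed(seed, 79L)),
      bp = function(Xtr, ytr)
        train_bp(Xtr, ytr, hidden = n_hidden_bp, max_epochs = bp_epochs,
                 seed = derive_seed(seed, 83L)),
      stop_nirmeat("run_experiment: unknown family ", fam))
    if (include_baseline) {
      baseline[[fam]] <- evaluate_learner(fit_fun, data, folds, fold_seed,
                                          calibration_cv = calibration_cv)
    }
    if (optimize) {
      opt <- optimize_model(if (fam == "svm") svm_kind else fam,
                            data$cal$X, data$cal$y,
                            sample_ids = data$cal$ids, folds = folds,
                            seed = derive_seed(seed, 89L),
                            level = ssa_level,
                            n_hidden = if (fam == "elm") n_hidden_elm else
                              n_hidden_bp,
                            bp_final_epochs = bp_epochs,
                            ssa_n = ssa_n, ssa_iter = ssa_iter)
      searches[[fam]] <- opt
      opt_fit <- switch(fam,
        svm = function(Xtr, ytr)
          train_svm(Xtr, ytr, c = opt$best_position[1],
                    g = opt$best_position[2]),
        elm = function(Xtr, ytr)
          train_elm(Xtr, ytr, n_hidden = n_hidden_elm,
                    weights = opt$model$weights),
        bp = function(Xtr, ytr)
          train_bp(Xtr, ytr, hidden = n_hidden_bp,
                   init_weights = opt$best_position,
                   max_epochs = bp_epochs))
      optimized[[fam]] <- evaluate_learner(opt_fit, data, folds, fold_seed,
                                           calibration_cv = calibration_cv)
    }
  }
  list(data = data, baseline = baseline,
       optimized = if (optimize) optimized else NULL,
       searches = if (optimize) searches else NULL)
}
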