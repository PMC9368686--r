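#' Stratified sample-level calibration/prediction split
#'
#' Splits samples (never spectra) 3:1 into calibration and prediction sets,
#' stratified so the design's per-set counts are reproduced deterministically:
#' by class for classification, by proportion x part for quantification.
#' Every spectrum later inherits its parent sample's membership, so the two
#' sets never share a sample.
#'
#' @param sample_table a [generate_design()] table (or any data.frame with
#'   `sample_id`, `class`, `part`, `proportion`).
#' @param ratio calibration fraction (default 3:1 = 0.75).
#' @param stratify_by `"class"` or `"proportion_part"`.
#' @param seed integer seed.
#' @return list with character vectors `calibration` and `prediction`.
#' @export
split_samples <- function(sample_table, ratio = 0.75,
                          stratify_by = c("class", "proportion_part"),
                          seed = 1L) {
  stratify_by <- match.arg(stratify_by)
  if (ratio <= 0 || ratio >= 1) {
    stop_nirmeat("split_samples: ratio must lie in (0, 1); both sets are required")
  }
  strata <- if (stratify_by == "class") {
    sample_table$class
  } else {
    paste(sample_table$proportion, sample_table$part, sep = "|")
  }
  cal <- character(0)
  pred <- character(0)
  for (s in unique(strata)) {
    ids <- sample_table$sample_id[strata == s]
    n <- length(ids)
    if (n < 4L) {
      stop_nirmeat(sprintf("split_samples: stratum '%s' has only %d samples (need >= 4)",
                           s, n))
    }
    n_cal <- round(ratio * n)
    if (n_cal < 1L || n_cal >= n) {
      stop_nirmeat(sprintf("split_samples: stratum '%s' cannot be split at ratio %g",
                           s, ratio))
    }
    perm <- with_local_seed(derive_seed(seed, 53L, which(unique(strata) == s)),
                            sample(ids))
    cal <- c(cal, perm[seq_len(n_cal)])
    pred <- c(pred, perm[(n_cal + 1L):n])
  }
  if (length(intersect(cal, pred))) {
    stop_nirmeat("split_samples: leakage detected (shared sample ids)")
  }
  list(calibration = cal, prediction = pred)
}

#' Confusion matrix and accuracy
#'
#' K x K count matrix (rows = truth, columns = prediction) in the declared
#' class order, overall accuracy (trace / total) and per-class accuracy
#' (row-normalised diagonal).
#'
#' @param truth,pred label vectors of equal length; every label must belong
#'   to `classes`.
#' @param classes class order of the matrix.
#' @return list of class `eval_fragment` with `confusion`, `accuracy`,
#'   `per_class`, `n`.
#' @export
confusion_and_accuracy <- function(truth, pred,
                                   classes = c("M", "P", "MP")) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (length(truth) != length(pred)) {
    stop_nirmeat("confusion_and_accuracy: length mismatch")
  }
  alien <- setdiff(unique(c(truth, pred)), classes)
  if (length(alien)) {
    stop_nirmeat("confusion_and_accuracy: label(s) outside the class set: ",
                 paste(alien, collapse = ", "))
  }
  cm <- table(factor(truth, classes), factor(pred, classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  acc <- sum(diag(cm)) / length(truth)
  per_class <- diag(cm) / rowSums(cm)
  structure(list(confusion = cm, accuracy = acc, per_class = per_class,
                 n = length(truth)),
            class = "eval_fragment")
}

#' Regression metrics for adulteration quantification
#'
#' RMSE in g/g and the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot` about the mean of the true values. With
#' zero-variance truth the R2 is undefined and reported as `NA` with a flag.
#'
#' @param truth,pred numeric vectors of equal length `>= 2` (mass fractions,
#'   g/g).
#' @return list of class `eval_fragment` with `rmse`, `r2`, `n` and
#'   `r2_defined`.
#' @export
regression_metrics <- function(truth, pred) {
  if (length(truth) != length(pred) || length(truth) < 2L) {
    stop_nirmeat("regression_metrics: need equal lengths >= 2")
  }
  rmse <- sqrt(mean((pred - truth)^2))
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot <= 0) {
    return(structure(list(rmse = rmse, r2 = NA_real_, n = length(truth),
                          r2_defined = FALSE),
                     class = "eval_fragment"))
  }
  r2 <- 1 - sum((pred - truth)^2) / ss_tot
  structure(list(rmse = rmse, r2 = r2, n = length(truth), r2_defined = TRUE),
            class = "eval_fragment")
}

#' Paired comparison of baseline and SSA-optimised reports
#'
#' Both report lists must share the evaluation protocol (task, split seed,
#' fold seed); deltas are optimised minus baseline for each metric and set.
#'
#' @param baseline,optimized named lists of `eval_report` objects (same
#'   names, e.g. `bp`, `elm`, `svm`).
#' @return `data.frame` with one row per (model, metric, set) triple.
#' @export
compare_models <- function(baseline, optimized) {
  if (!identical(sort(names(baseline)), sort(names(optimized)))) {
    stop_nirmeat("compare_models: model names differ between report lists")
  }
  rows <- list()
  for (nm in names(baseline)) {
    b <- baseline[[nm]]
    o <- optimized[[nm]]
    if (!identical(b$protocol, o$protocol)) {
      stop_nirmeat("compare_models: evaluation protocols differ for ", nm)
    }
    for (set in c("calibration", "prediction")) {
      fb <- b[[set]]
      fo <- o[[set]]
      metrics <- if (b$task == "classify") "accuracy" else c("r2", "rmse")
      for (m in metrics) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = nm, metric = m, set = set,
          baseline = fb[[m]], optimized = fo[[m]],
          delta = fo[[m]] - fb[[m]], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation report to disk
#'
#' Emits `metrics.json` (whole report, numbers preserved), plus
#' `confusion_<set>.csv` for classification or `predictions.csv` and
#' `errorbars.csv` (per true proportion: mean, sd, n of the predictions; the
#' predicted-vs-true scatter summary) for quantification.
#'
#' @param report an `eval_report` (see [evaluate_learner()]).
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  mj <- file.path(dir, "metrics.json")
  ser <- report
  ser$predictions <- NULL
  for (set in c("calibration", "prediction")) {
    if (!is.null(ser[[set]]$confusion)) {
      ser[[set]]$confusion <- as.data.frame(ser[[set]]$confusion)
    }
  }
  jsonlite::write_json(ser, mj, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- c(files, mj)
  if (report$task == "classify") {
    for (set in c("calibration", "prediction")) {
      f <- file.path(dir, sprintf("confusion_%s.csv", set))
      cm <- report[[set]]$confusion
      utils::write.csv(cbind(truth = rownames(cm), as.data.frame(cm)),
                       f, row.names = FALSE)
      files <- c(files, f)
    }
  } else {
    pf <- file.path(dir, "predictions.csv")
    utils::write.csv(report$predictions, pf, row.names = FALSE)
    files <- c(files, pf)
    pr <- report$predictions[report$predictions$set == "prediction", ]
    agg <- do.call(rbind, lapply(split(pr, pr$truth), function(gdf)
      data.frame(proportion = gdf$truth[1L], mean_pred = mean(gdf$pred),
                 sd_pred = stats::sd(gdf$pred), n = nrow(gdf))))
    ef <- file.path(dir, "errorbars.csv")
    utils::write.csv(agg, ef, row.names = FALSE)
    files <- c(files, ef)
  }
  invisible(files)
}
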