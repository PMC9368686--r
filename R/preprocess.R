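#' Preprocessing configuration
#'
#' Spectra are preprocessed with a first derivative followed by
#' multiplicative scatter correction ("1D + MSC"). The derivative estimator,
#' its window, and the stage order are configurable; defaults are a
#' Savitzky-Golay derivative (window 15 bands, polynomial order 2), robust to
#' pixel noise, applied before MSC.
#'
#' @param derivative apply the first-derivative stage?
#' @param derivative_method `"sg"` (Savitzky-Golay smoothing-polynomial
#'   derivative, keeps the band grid) or `"diff"` (first difference, one band
#'   shorter, midpoint wavelengths).
#' @param window odd window length in bands (`"sg"` only), `> polyorder`.
#' @param polyorder polynomial order of the smoothing fit.
#' @param msc apply multiplicative scatter correction?
#' @param msc_reference `"calibration-mean"` (bandwise mean of the spectra
#'   the pipeline state is fitted on), `"self"` (each spectrum its own
#'   reference; the identity transform), or a numeric reference spectrum.
#' @param stage_order character vector ordering the enabled stages; default
#'   derivative first, matching the method's name.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(derivative = TRUE, derivative_method = c("sg", "diff"),
                              window = 15L, polyorder = 2L,
                              msc = TRUE, msc_reference = "calibration-mean",
                              stage_order = c("derivative", "msc")) {
  derivative_method <- match.arg(derivative_method)
  if (window %% 2L != 1L || window <= polyorder) {
    stop_nirmeat("preprocess_config: window must be odd and > polyorder")
  }
  if (!all(stage_order %in% c("derivative", "msc"))) {
    stop_nirmeat("preprocess_config: unknown stage in stage_order")
  }
  structure(list(derivative = derivative,
                 derivative_method = derivative_method,
                 window = as.integer(window),
                 polyorder = as.integer(polyorder),
                 msc = msc, msc_reference = msc_reference,
                 stage_order = stage_order),
            class = "preprocess_config")
}

#' First derivative of spectra with respect to wavelength
#'
#' Removes additive baseline offsets (derivative of a constant is zero).
#' The Savitzky-Golay method fits a local polynomial per band and returns its
#' analytic derivative, keeping the band grid; the difference method returns
#' forward differences on midpoint wavelengths.
#'
#' @param spectra a `spectrum_set`.
#' @param config a [preprocess_config()].
#' @return a `spectrum_set` in derivative units (reflectance per nm).
#' @export
first_derivative <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(spectra, "spectrum_set"))
  wl <- spectra$wavelengths
  nb <- length(wl)
  x <- spectra$spectra
  if (config$derivative_method == "sg") {
    if (config$window >= nb) {
      stop_nirmeat("first_derivative: window must be smaller than band count")
    }
    dw <- diff(wl)
    if (max(abs(dw - mean(dw))) > 1e-6 * mean(dw)) {
      stop_nirmeat("first_derivative: Savitzky-Golay needs an even band grid")
    }
    filt <- signal::sgolay(p = config$polyorder, n = config$window, m = 1L,
                           ts = mean(dw))
    der <- t(apply(x, 1L, function(v) signal::filter(filt, v)))
    out_wl <- wl
  } else {
    if (nb < 2L) stop_nirmeat("first_derivative: need >= 2 bands")
    der <- t(apply(x, 1L, diff)) / rep(diff(wl), each = nrow(x))
    if (nrow(x) == 1L) der <- matrix(der, nrow = 1L)
    out_wl <- (wl[-1L] + wl[-nb]) / 2
  }
  spectrum_set(der, out_wl, spectra$meta,
               processing = c(spectra$processing,
                              list(list(stage = "derivative",
                                        method = config$derivative_method,
                                        window = config$window,
                                        polyorder = config$polyorder))))
}

#' Fit the MSC reference spectrum
#'
#' Bandwise mean of the calibration-set spectra. The reference is frozen and
#' reused to correct prediction spectra so no information flows from the
#' prediction set into the transform.
#'
#' @param calibration_spectra a `spectrum_set` or numeric matrix with at
#'   least two spectra.
#' @return numeric reference spectrum.
#' @export
fit_msc_reference <- function(calibration_spectra) {
  x <- if (inherits(calibration_spectra, "spectrum_set")) {
    calibration_spectra$spectra
  } else {
    as.matrix(calibration_spectra)
  }
  if (nrow(x) < 2L) {
    stop_nirmeat("fit_msc_reference: need at least 2 calibration spectra")
  }
  colMeans(x)
}

#' Multiplicative scatter correction
#'
#' Per spectrum, ordinary least squares of the spectrum on the reference over
#' bands, `x = a + b * ref`, then inversion `(x - a) / b`, removing
#' scatter-induced offset and gain. Spectra whose slope `|b|` falls below
#' `tol` cannot be corrected; they are dropped with a warning and their row
#' indices recorded in attribute `excluded`.
#'
#' @param spectra a `spectrum_set` or numeric matrix.
#' @param reference numeric reference spectrum, same band count.
#' @param tol slope tolerance below which a spectrum is flagged.
#' @return corrected spectra, same class as the input.
#' @export
msc <- function(spectra, reference, tol = 1e-10) {
  is_set <- inherits(spectra, "spectrum_set")
  x <- if (is_set) spectra$spectra else as.matrix(spectra)
  reference <- as.numeric(reference)
  if (ncol(x) != length(reference)) {
    stop_nirmeat("msc: reference length must equal the band count")
  }
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom <= 0) stop_nirmeat("msc: constant reference spectrum")
  xm <- rowMeans(x)
  b <- as.vector((x %*% rc)) / denom
  a <- xm - b * mean(reference)
  bad <- which(abs(b) < tol)
  if (length(bad)) {
    warning(sprintf("msc: excluded %d spectrum(s) with |slope| < %g",
                    length(bad), tol))
    keep <- setdiff(seq_len(nrow(x)), bad)
  } else {
    keep <- seq_len(nrow(x))
  }
  out <- (x[keep, , drop = FALSE] - a[keep]) / b[keep]
  if (is_set) {
    res <- spectrum_set(out, spectra$wavelengths,
                        spectra$meta[keep, , drop = FALSE],
                        processing = c(spectra$processing,
                                       list(list(stage = "msc"))))
    if (length(bad)) attr(res, "excluded") <- bad
    res
  } else {
    if (length(bad)) attr(out, "excluded") <- bad
    out
  }
}

#' Full preprocessing pipeline with frozen state
#'
#' Applies the enabled stages in `config$stage_order`. On a calibration set
#' (no `frozen_state`), the MSC reference is fitted from the spectra entering
#' the MSC stage and returned in the state; on a prediction set, pass the
#' calibration state so both sets are transformed identically.
#'
#' @param spectra a `spectrum_set`.
#' @param config a [preprocess_config()].
#' @param frozen_state state list returned by a previous calibration run.
#' @return list with `spectra` (processed `spectrum_set`) and `state`.
#' @export
preprocess_pipeline <- function(spectra, config = preprocess_config(),
                                frozen_state = NULL) {
  stopifnot(inherits(spectra, "spectrum_set"))
  state <- frozen_state %||% list(config = config, reference = NULL)
  out <- spectra
  for (stage in config$stage_order) {
    if (stage == "derivative" && isTRUE(config$derivative)) {
      out <- first_derivative(out, config)
    } else if (stage == "msc" && isTRUE(config$msc)) {
      ref_spec <- config$msc_reference
      if (is.numeric(ref_spec)) {
        reference <- ref_spec
      } else if (identical(ref_spec, "self")) {
        reference <- NULL
      } else if (identical(ref_spec, "calibration-mean")) {
        if (is.null(frozen_state)) {
          reference <- fit_msc_reference(out)
          state$reference <- reference
        } else {
          reference <- frozen_state$reference
          if (is.null(reference)) {
            stop_nirmeat("preprocess_pipeline: frozen_state lacks the MSC reference")
          }
        }
      } else {
        stop_nirmeat("preprocess_pipeline: unknown msc_reference")
      }
      if (!is.null(reference)) out <- msc(out, reference)
      # "self": each spectrum regressed on itself gives a = 0, b = 1 exactly
    }
  }
  out$processing <- c(out$processing,
                      list(list(stage = "pipeline_done",
                                order = config$stage_order)))
  list(spectra = out, state = state)
}
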