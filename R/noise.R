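#' Scatter and noise model for generated spectra
#'
#' Per-spectrum multiplicative gain (lognormal around 1), additive offset,
#' slow polynomial baseline drift and i.i.d. per-band pixel noise. These are
#' exactly the artifacts that multiplicative scatter correction and the first
#' derivative are meant to remove, so the generator gives the preprocessing
#' something real to correct. With every parameter 0 the corruption is the
#' identity.
#'
#' @param mult_scatter_sd sd of `log(b)` for the multiplicative factor `b`.
#' @param add_scatter_sd sd (reflectance units) of the additive offset `a`.
#' @param pixel_noise_sd sd (reflectance units) of the per-band noise.
#' @param drift_amplitude scale (reflectance units) of the slow quadratic
#'   baseline drift.
#' @return object of class `scatter_noise_model`.
#' @export
scatter_noise_model <- function(mult_scatter_sd = 0.08,
                                add_scatter_sd = 0.02,
                                pixel_noise_sd = 0.002,
                                drift_amplitude = 0.01) {
  for (nm in c("mult_scatter_sd", "add_scatter_sd", "pixel_noise_sd",
               "drift_amplitude")) {
    check_number(get(nm), nm, lo = 0)
  }
  structure(list(mult_scatter_sd = mult_scatter_sd,
                 add_scatter_sd = add_scatter_sd,
                 pixel_noise_sd = pixel_noise_sd,
                 drift_amplitude = drift_amplitude),
            class = "scatter_noise_model")
}

#' Apply scatter/noise corruption to spectra
#'
#' Returns `a + b * spec + drift + eps` per spectrum, with draws governed by
#' the noise model; deterministic under a fixed seed. Final values are clipped
#' into (0, 1.5] (a warning reports how many values were clipped).
#'
#' @param spec a reflectance vector or an N x B matrix (one spectrum per row).
#' @param noise a [scatter_noise_model()].
#' @param seed integer seed or `NULL` (use current RNG stream).
#' @param draws optional list overriding the random draws (for exact tests):
#'   `a`, `b` (length-N), `drift_coef` (N x 2), `eps` (N x B). Omitted
#'   components are drawn from the model.
#' @return corrupted spectra, same shape as the input.
#' @export
corrupt_spectrum <- function(spec, noise, seed = NULL, draws = NULL) {
  stopifnot(inherits(noise, "scatter_noise_model"))
  vec_in <- is.null(dim(spec))
  x <- if (vec_in) matrix(spec, nrow = 1L) else as.matrix(spec)
  n <- nrow(x)
  b_ <- ncol(x)
  out <- with_local_seed(seed, {
    a <- draws$a %||% rnorm(n, 0, noise$add_scatter_sd)
    b <- draws$b %||% exp(rnorm(n, 0, noise$mult_scatter_sd))
    dc <- draws$drift_coef %||%
      matrix(rnorm(2L * n), n, 2L) * noise$drift_amplitude
    eps <- draws$eps %||% matrix(rnorm(n * b_, 0, noise$pixel_noise_sd), n, b_)
    u <- seq(-1, 1, length.out = b_)
    drift <- dc[, 1L, drop = FALSE] %*% rbind(u) +
      dc[, 2L, drop = FALSE] %*% rbind(2 * u^2 - 1)
    x * b + a + drift + eps
  })
  n_clip <- sum(out <= 0 | out > 1.5)
  if (n_clip > 0) {
    warning(sprintf("corrupt_spectrum: clipped %d value(s) into (0, 1.5]",
                    n_clip))
    out[out <= 0] <- 1e-6
    out[out > 1.5] <- 1.5
  }
  if (vec_in) drop(out) else out
}
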