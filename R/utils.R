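#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded helpers never perturb the global random stream. A `NULL` seed means
#' "use the current stream".
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed
#'
#' One user-facing seed drives every random stage; per-sample and per-stage
#' streams are derived from it with a Lehmer-style hash so that changing one
#' stage never reshuffles another. Result always lies in [1, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param ... integer stream keys (e.g. sample index, stage code).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  keys <- c(...)
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (k in keys) {
    s <- (s * 48271 + (as.double(k) %% 2147483647) * 69621 + 1) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based threshold maximising between-class variance; used by the
#' band-math ROI segmentation. Returns the upper edge of the background bin.
#'
#' @param x numeric vector (non-finite values dropped).
#' @param n_bins number of histogram bins.
#' @return threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("otsu_threshold: no finite values")
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  br[k + 1L]
}

stop_nirmeat <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop_nirmeat(sprintf("`%s` must be a single finite number in [%g, %g]",
                         name, lo, hi))
  }
  invisible(x)
}
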