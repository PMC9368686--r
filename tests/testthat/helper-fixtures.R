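# Shared fixtures: small models and designs used across test files.

tiny_wavelengths <- function(n = 40L) seq(1000, 2500, length.out = n)

tiny_endmembers <- function(n = 40L) {
  endmember_model(wavelengths = tiny_wavelengths(n))
}

# a design small enough for fast end-to-end runs but with >= 4 samples per
# stratum in both split modes
small_design <- function() {
  sample_design(n_mutton = 6L, n_pork_per_part = 3L,
                parts = c("front_leg", "hind_leg"),
                proportions = c(0.05, 0.20, 0.40),
                replicates_per_cell = 4L, blocks_per_sample = 5L)
}

quiet_noise <- function() {
  scatter_noise_model(mult_scatter_sd = 0, add_scatter_sd = 0,
                      pixel_noise_sd = 0, drift_amplitude = 0)
}

random_spectrum_set <- function(n = 5L, bands = 40L, seed = 1L) {
  withr::with_seed(seed, {
    spectrum_set(matrix(runif(n * bands, 0.2, 0.8), n, bands),
                 tiny_wavelengths(bands))
  })
}

# two well-separated Gaussian blobs in 2-D
two_blobs <- function(n_per = 30L, sep = 3, seed = 1L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per), n_per, 2),
               matrix(rnorm(2 * n_per), n_per, 2) + sep)
    y <- factor(rep(c("a", "b"), each = n_per))
    list(X = X, y = y)
  })
}
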