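#' Generate pixel-level spectra for every sample of a design
#'
#' Each sample's noiseless mixture spectrum (per its class and proportion) is
#' corrupted `pixels_per_sample` times under a per-sample sub-seed, emulating
#' the pixel spectra inside a sample's region of interest.
#'
#' @param design_table output of [generate_design()].
#' @param model an [endmember_model()].
#' @param noise a [scatter_noise_model()].
#' @param pixels_per_sample pixel spectra per sample; must be at least the
#'   design's `blocks_per_sample` or later block averaging is impossible.
#' @param seed master integer seed.
#' @return a `spectrum_set` of pixel spectra with metadata columns
#'   `sample_id`, `class`, `part`, `proportion`, `pixel_id`.
#' @export
generate_sample_spectra <- function(design_table, model, noise,
                                    pixels_per_sample = 100L, seed = 1L) {
  stopifnot(inherits(model, "endmember_model"),
            inherits(noise, "scatter_noise_model"))
  des <- attr(design_table, "design")
  blocks <- if (!is.null(des)) des$blocks_per_sample else 1L
  if (pixels_per_sample < blocks) {
    stop_nirmeat(sprintf(
      "generate_sample_spectra: pixels_per_sample (%d) < blocks_per_sample (%d)",
      pixels_per_sample, blocks))
  }
  mutton <- generate_endmembers(model, "mutton")
  pork_e <- generate_endmembers(model, "pork_essence")
  nsamp <- nrow(design_table)
  nb <- length(model$wavelengths)
  out <- matrix(0, nsamp * pixels_per_sample, nb)
  for (i in seq_len(nsamp)) {
    p <- design_table$proportion[i]
    pure <- mix_spectrum(p, mutton, pork_e)
    block <- matrix(pure, pixels_per_sample, nb, byrow = TRUE)
    rows <- (i - 1L) * pixels_per_sample + seq_len(pixels_per_sample)
    out[rows, ] <- corrupt_spectrum(block, noise,
                                    seed = derive_seed(seed, 11L, i))
  }
  meta <- design_table[rep(seq_len(nsamp), each = pixels_per_sample),
                       c("sample_id", "class", "part", "proportion")]
  meta$pixel_id <- rep(seq_len(pixels_per_sample), nsamp)
  rownames(meta) <- NULL
  spectrum_set(out, model$wavelengths, meta,
               processing = list(list(stage = "synthetic_pixels")))
}

# Random near-equal partition of n items into k blocks; the first n %% k
# blocks receive one extra item.
partition_blocks <- function(n, k, seed = NULL) {
  if (k < 1L || k > n) {
    stop_nirmeat(sprintf("cannot split %d pixels into %d blocks", n, k))
  }
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' Block-mean spectra from pixel-level spectra
#'
#' Per sample, the pixel spectra are randomly permuted (seeded, per-sample
#' sub-stream) and partitioned into `k` near-equal blocks; each block's mean
#' spectrum becomes one observation. This is the data-expansion step that
#' turns one sample into `k` representative spectra.
#'
#' @param pixel_set `spectrum_set` of pixel spectra with a `sample_id` column.
#' @param k number of blocks per sample.
#' @param seed master integer seed.
#' @return a `spectrum_set` of block means with metadata `sample_id`, `class`,
#'   `part`, `proportion`, `block_id`, `block_n` (pixels averaged).
#' @export
block_mean_spectra <- function(pixel_set, k = 10L, seed = 1L) {
  stopifnot(inherits(pixel_set, "spectrum_set"))
  ids <- unique(pixel_set$meta$sample_id)
  res <- vector("list", length(ids))
  metas <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    rows <- which(pixel_set$meta$sample_id == ids[s])
    blocks <- partition_blocks(length(rows), k,
                               seed = derive_seed(seed, 23L, s))
    mm <- t(vapply(blocks, function(ix)
      colMeans(pixel_set$spectra[rows[ix], , drop = FALSE]),
      numeric(ncol(pixel_set$spectra))))
    res[[s]] <- mm
    m1 <- pixel_set$meta[rows[1L],
                         intersect(c("sample_id", "class", "part",
                                     "proportion"), names(pixel_set$meta)),
                         drop = FALSE]
    meta <- m1[rep(1L, k), , drop = FALSE]
    meta$block_id <- seq_len(k)
    meta$block_n <- vapply(blocks, length, integer(1))
    metas[[s]] <- meta
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  spectrum_set(do.call(rbind, res), pixel_set$wavelengths, meta,
               processing = c(pixel_set$processing,
                              list(list(stage = "block_means", k = k))))
}

#' Geometry of a synthetic hyperspectral cube
#'
#' @param rows,cols image size in pixels.
#' @param radius radius (pixels) of the circular meat disc.
#' @param n_fat number of small high-reflectance fat specks inside the disc.
#' @param n_bright number of single-pixel bright (specular) spots.
#' @param fat_radius radius of each fat speck in pixels.
#' @param background_reflectance reflectance of the black cardboard backdrop.
#' @param white_level,black_level nominal levels of the white/black reference
#'   frames.
#' @param ref_noise_sd per-pixel-per-band noise of the reference frames.
#' @return list of class `cube_geometry`.
#' @export
cube_geometry <- function(rows = 64L, cols = 64L, radius = 24L,
                          n_fat = 3L, n_bright = 2L, fat_radius = 1L,
                          background_reflectance = 0.05,
                          white_level = 0.95, black_level = 0.02,
                          ref_noise_sd = 0.002) {
  structure(as.list(environment()), class = "cube_geometry")
}

#' Generate a raw hyperspectral cube with reference frames and truth mask
#'
#' Renders one sample as a disc of corrupted mixture spectra on a dark
#' background, adds flat high-reflectance fat specks and bright spots, then
#' converts the scene to "raw counts" through synthetic white/black reference
#' frames so that [calibrate()] recovers reflectance. The returned truth mask
#' marks muscle pixels only (disc minus fat/bright pixels).
#'
#' @param sample_row one row of a [generate_design()] table.
#' @param model an [endmember_model()].
#' @param noise a [scatter_noise_model()].
#' @param geometry a [cube_geometry()].
#' @param seed integer seed.
#' @return list with elements `raw` (an `hsi_cube` of kind `"raw"`), `refs`
#'   (a [calibration_refs()]), `truth_mask` (logical matrix, muscle pixels),
#'   `disc_mask` (logical matrix, whole disc) and `reflectance` (the noisy
#'   ground-truth reflectance cube).
#' @export
generate_cube <- function(sample_row, model, noise,
                          geometry = cube_geometry(), seed = 1L) {
  stopifnot(inherits(model, "endmember_model"),
            inherits(geometry, "cube_geometry"))
  g <- geometry
  if (2L * (g$radius + 1L) >= min(g$rows, g$cols)) {
    stop_nirmeat("generate_cube: disc does not fit inside the image")
  }
  nb <- length(model$wavelengths)
  wl <- model$wavelengths
  mutton <- generate_endmembers(model, "mutton")
  pork_e <- generate_endmembers(model, "pork_essence")
  pure <- mix_spectrum(sample_row$proportion, mutton, pork_e)

  cr <- (g$rows + 1) / 2
  cc <- (g$cols + 1) / 2
  rr <- matrix(seq_len(g$rows), g$rows, g$cols)
  cc_m <- matrix(seq_len(g$cols), g$rows, g$cols, byrow = TRUE)
  dist2 <- (rr - cr)^2 + (cc_m - cc)^2
  disc <- dist2 <= g$radius^2

  with_local_seed(seed, {
    refl <- array(0, dim = c(g$rows, g$cols, nb))
    # background: dark, slightly noisy cardboard
    nbg <- sum(!disc)
    bg <- matrix(pmax(g$background_reflectance +
                        rnorm(nbg * nb, 0, 0.005), 1e-4), nbg, nb)
    # meat pixels: corrupted mixture spectra
    nfg <- sum(disc)
    meat <- corrupt_spectrum(matrix(pure, nfg, nb, byrow = TRUE), noise)
    idx_bg <- which(!disc)
    idx_fg <- which(disc)
    for (b in seq_len(nb)) {
      plane <- matrix(0, g$rows, g$cols)
      plane[idx_bg] <- bg[, b]
      plane[idx_fg] <- meat[, b]
      refl[, , b] <- plane
    }
    # fat specks: small flat bright discs well inside the meat
    speck_px <- integer(0)
    if (g$n_fat > 0) {
      inner <- which(dist2 <= (g$radius - g$fat_radius - 2L)^2)
      centers <- sample(inner, g$n_fat)
      for (ct in centers) {
        r0 <- (ct - 1L) %% g$rows + 1L
        c0 <- (ct - 1L) %/% g$rows + 1L
        px <- which((rr - r0)^2 + (cc_m - c0)^2 <= g$fat_radius^2)
        speck_px <- union(speck_px, px)
      }
      fat_spec <- 0.85 - 0.05 * (wl - min(wl)) / diff(range(wl))
      for (b in seq_len(nb)) {
        plane <- refl[, , b]
        plane[speck_px] <- fat_spec[b] + rnorm(length(speck_px), 0, 0.01)
        refl[, , b] <- plane
      }
    }
    bright_px <- integer(0)
    if (g$n_bright > 0) {
      inner <- setdiff(which(dist2 <= (g$radius - 2L)^2), speck_px)
      bright_px <- sample(inner, g$n_bright)
      for (b in seq_len(nb)) {
        plane <- refl[, , b]
        plane[bright_px] <- 0.98 + rnorm(length(bright_px), 0, 0.005)
        refl[, , b] <- plane
      }
    }
    white <- array(g$white_level + rnorm(g$rows * g$cols * nb, 0,
                                         g$ref_noise_sd),
                   dim = c(g$rows, g$cols, nb))
    black <- array(pmax(g$black_level + rnorm(g$rows * g$cols * nb, 0,
                                              g$ref_noise_sd), 0),
                   dim = c(g$rows, g$cols, nb))
    raw <- black + refl * (white - black)
    truth <- disc
    truth[speck_px] <- FALSE
    truth[bright_px] <- FALSE
    list(raw = hsi_cube(raw, wl, kind = "raw"),
         refs = calibration_refs(white, black),
         truth_mask = truth, disc_mask = disc,
         reflectance = hsi_cube(refl, wl, kind = "calibrated"))
  })
}
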