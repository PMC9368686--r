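test_that("endmember spectra carry the four absorption dips at shared positions", {
  m <- endmember_model()
  wl <- m$wavelengths
  mutton <- generate_endmembers(m, "mutton")
  pork <- generate_endmembers(m, "pork")
  expect_true(all(mutton > 0 & mutton <= 1))
  expect_true(all(pork > 0 & pork <= 1))
  for (ctr in m$peak_centers) {
    band <- which.min(abs(wl - ctr))
    win <- max(1, band - 5):min(length(wl), band + 5)
    # a local reflectance minimum at (or immediately next to) the peak band
    expect_lte(abs(win[which.min(mutton[win])] - band), 1)
    expect_lte(abs(win[which.min(pork[win])] - band), 1)
    # same argmin band for both classes, distinct reflectance levels
    expect_identical(win[which.min(mutton[win])], win[which.min(pork[win])])
    expect_gt(abs(mutton[band] - pork[band]), 0.01)
  }
})

test_that("a zero-amplitude flat model returns the constant baseline spectrum", {
  m <- endmember_model(peak_amplitudes = list(mutton = rep(0, 4),
                                              pork = rep(0, 4)),
                       baseline = list(mutton = c(0.301029995663981, 0),
                                       pork = c(0.301029995663981, 0)),
                       essence_shift = 0)
  expect_equal(generate_endmembers(m, "mutton"),
               rep(0.5, length(m$wavelengths)), tolerance = 1e-12)
})

test_that("essence treatment perturbs the pork endmember additively in absorbance", {
  m <- endmember_model()
  pork <- generate_endmembers(m, "pork")
  pork_e <- generate_endmembers(m, "pork_essence")
  expect_equal(-log10(pork_e) + log10(pork),
               rep(m$essence_shift, length(pork)), tolerance = 1e-12)
  expect_error(generate_endmembers(m, "beef"), "class_label")
})

test_that("mix_spectrum is linear in absorbance with exact boundaries", {
  m <- tiny_endmembers()
  mutton <- generate_endmembers(m, "mutton")
  pork <- generate_endmembers(m, "pork_essence")
  expect_identical(mix_spectrum(0, mutton, pork), mutton)
  expect_identical(mix_spectrum(1, mutton, pork), pork)
  # closed form: flat endmembers 0.4 / 0.9 at p = 0.2
  flat_a <- rep(0.4, 10)
  flat_b <- rep(0.9, 10)
  expect_equal(mix_spectrum(0.2, flat_a, flat_b),
               rep(10^(0.2 * log10(0.9) + 0.8 * log10(0.4)), 10),
               tolerance = 1e-14)
  expect_error(mix_spectrum(1.2, mutton, pork), "p")
  expect_error(mix_spectrum(-0.1, mutton, pork), "p")
})

test_that("noise-free mixing is exactly invertible by 1-D least squares in absorbance", {
  m <- tiny_endmembers()
  mutton <- -log10(generate_endmembers(m, "mutton"))
  pork <- -log10(generate_endmembers(m, "pork_essence"))
  for (p in c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40)) {
    mixed <- -log10(mix_spectrum(p, generate_endmembers(m, "mutton"),
                                 generate_endmembers(m, "pork_essence")))
    dirvec <- pork - mutton
    p_hat <- sum((mixed - mutton) * dirvec) / sum(dirvec^2)
    expect_equal(p_hat, p, tolerance = 1e-10)
  }
})

test_that("corrupt_spectrum honours the identity, determinism and affine contracts", {
  m <- tiny_endmembers()
  spec <- generate_endmembers(m, "mutton")
  none <- quiet_noise()
  expect_identical(corrupt_spectrum(spec, none, seed = 1L), spec)
  noisy <- scatter_noise_model()
  a <- corrupt_spectrum(spec, noisy, seed = 7L)
  b <- corrupt_spectrum(spec, noisy, seed = 7L)
  expect_identical(a, b)
  expect_false(identical(a, corrupt_spectrum(spec, noisy, seed = 8L)))
  # fixed draws: pure affine map
  forced <- corrupt_spectrum(spec, none, draws = list(a = 0.1, b = 2))
  expect_equal(forced, pmin(0.1 + 2 * spec, 1.5), tolerance = 1e-14)
})

test_that("mean of corrupted spectra converges to the clean spectrum", {
  m <- tiny_endmembers()
  spec <- generate_endmembers(m, "mutton")
  noise <- scatter_noise_model(mult_scatter_sd = 0.05, add_scatter_sd = 0.01,
                               pixel_noise_sd = 0.005,
                               drift_amplitude = 0.005)
  reps_small <- corrupt_spectrum(matrix(spec, 50, length(spec),
                                        byrow = TRUE), noise, seed = 1L)
  reps_big <- corrupt_spectrum(matrix(spec, 2000, length(spec),
                                      byrow = TRUE), noise, seed = 2L)
  # b is lognormal: E[b] = exp(sd^2/2), so the expected mean spectrum is
  # exp(sd^2/2) * spec
  target <- exp(0.05^2 / 2) * spec
  mad_small <- mean(abs(colMeans(reps_small) - target))
  mad_big <- mean(abs(colMeans(reps_big) - target))
  expect_lt(mad_big, mad_small)
  expect_lt(mad_big, 0.002)
})

test_that("generate_design reproduces the printed sample structure and is pure", {
  tab <- generate_design(sample_design())
  expect_identical(nrow(tab), 192L)
  expect_identical(sum(tab$class == "MP"), 144L)
  expect_identical(sum(tab$class == "M"), 24L)
  expect_identical(sum(tab$class == "P"), 24L)
  expect_identical(anyDuplicated(tab$sample_id), 0L)
  # pork allocated evenly across parts
  expect_true(all(table(tab$part[tab$class == "P"]) == 8L))
  expect_true(all(table(tab$part[tab$class == "MP"],
                        tab$proportion[tab$class == "MP"]) == 8L))
  expect_identical(tab, generate_design(sample_design()))
  # single-cell design
  tiny <- generate_design(sample_design(n_mutton = 1, n_pork_per_part = 1,
                                        parts = "back", proportions = 0.1,
                                        replicates_per_cell = 1))
  expect_identical(sum(tiny$class == "MP"), 1L)
})

test_that("generate_sample_spectra sizes, tagging and pixel-mean convergence", {
  m <- tiny_endmembers()
  d <- small_design()
  tab <- generate_design(d)
  expect_error(generate_sample_spectra(tab, m, quiet_noise(),
                                       pixels_per_sample = 2L),
               "blocks_per_sample")
  px <- generate_sample_spectra(tab, m, quiet_noise(),
                                pixels_per_sample = 8L, seed = 1L)
  expect_identical(nrow(px$spectra), nrow(tab) * 8L)
  # noise off: every pixel equals the sample's mixture spectrum
  one <- px$spectra[px$meta$sample_id == tab$sample_id[1L], ]
  expect_true(all(apply(one, 2L, function(col) diff(range(col)) == 0)))
  # class-conditional means are distinct at the 1520 nm band
  noisy <- generate_sample_spectra(tab, m, scatter_noise_model(),
                                   pixels_per_sample = 30L, seed = 2L)
  band <- which.min(abs(noisy$wavelengths - 1520))
  mns <- tapply(noisy$spectra[, band], noisy$meta$class, mean)
  expect_gt(abs(mns[["M"]] - mns[["P"]]), 0.02)
  expect_true(mns[["MP"]] > min(mns[["M"]], mns[["P"]]) &&
                mns[["MP"]] < max(mns[["M"]], mns[["P"]]))
})

test_that("block_mean_spectra partitions pixels into near-equal seeded blocks", {
  m <- tiny_endmembers()
  tab <- generate_design(small_design())
  px <- generate_sample_spectra(tab, m, scatter_noise_model(),
                                pixels_per_sample = 23L, seed = 1L)
  bm <- block_mean_spectra(px, k = 5L, seed = 9L)
  expect_identical(nrow(bm$spectra), nrow(tab) * 5L)
  expect_true(all(bm$meta$block_n %in% c(4L, 5L)))
  expect_identical(bm$spectra, block_mean_spectra(px, k = 5L, seed = 9L)$spectra)
  # weighted mean of block means equals the overall pixel mean per sample
  sid <- tab$sample_id[3L]
  rows <- bm$meta$sample_id == sid
  recon <- colSums(bm$spectra[rows, ] * bm$meta$block_n[rows]) /
    sum(bm$meta$block_n[rows])
  expect_equal(recon, colMeans(px$spectra[px$meta$sample_id == sid, ]),
               tolerance = 1e-12)
})

test_that("spectrum sets round-trip through CSV with metadata intact", {
  m <- tiny_endmembers()
  tab <- generate_design(small_design())
  rows <- c(which(tab$class == "M")[1L], which(tab$class == "MP")[1L])
  px <- generate_sample_spectra(tab[rows, ], m, scatter_noise_model(),
                                pixels_per_sample = 6L, seed = 2L)
  path <- file.path(withr::local_tempdir(), "spectra.csv")
  write_spectra_csv(px, path)
  back <- read_spectra_csv(path)
  expect_equal(back$spectra, px$spectra, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$wavelengths, px$wavelengths, tolerance = 1e-9)
  expect_identical(back$meta$sample_id, px$meta$sample_id)
  expect_equal(back$meta$proportion, px$meta$proportion)
})

test_that("generated cubes have the declared geometry and brightness ordering", {
  m <- tiny_endmembers(60L)
  tab <- generate_design(small_design())
  geo <- cube_geometry(rows = 40L, cols = 40L, radius = 14L, n_fat = 0L,
                       n_bright = 0L)
  cube <- generate_cube(tab[2L, ], m, scatter_noise_model(), geo, seed = 4L)
  expect_identical(dim(cube$raw$data)[3], length(m$wavelengths))
  # no specks: truth mask is exactly the disc
  expect_identical(cube$truth_mask, cube$disc_mask)
  # disc brighter than backdrop at every band
  refl <- cube$reflectance$data
  for (b in seq_len(dim(refl)[3])) {
    plane <- refl[, , b]
    expect_gt(mean(plane[cube$disc_mask]), mean(plane[!cube$disc_mask]))
  }
  expect_error(generate_cube(tab[2L, ], m, scatter_noise_model(),
                             cube_geometry(rows = 20L, cols = 20L,
                                           radius = 12L), seed = 1L),
               "disc")
})
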