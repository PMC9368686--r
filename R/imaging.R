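#' Hyperspectral cube container
#'
#' @param data numeric array, rows x cols x bands.
#' @param wavelengths band centres in nm, length `dim(data)[3]`.
#' @param kind `"raw"` (counts) or `"calibrated"` (reflectance).
#' @return object of class `hsi_cube`.
#' @export
hsi_cube <- function(data, wavelengths, kind = c("raw", "calibrated")) {
  kind <- match.arg(kind)
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop_nirmeat("hsi_cube: data must be a rows x cols x bands array")
  }
  if (dim(data)[3] != length(wavelengths)) {
    stop_nirmeat("hsi_cube: band count must equal length(wavelengths)")
  }
  if (kind == "calibrated" && any(!is.finite(data))) {
    stop_nirmeat("hsi_cube: calibrated values must be finite")
  }
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 kind = kind), class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube %s> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              x$kind, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' White/black reference frames for reflectance calibration
#'
#' @param white,black numeric arrays matching the raw cube's dimensions:
#'   the full-white (PTFE board) and full-black (lens cap) reference images.
#' @return object of class `calibration_refs`.
#' @export
calibration_refs <- function(white, black) {
  white <- as.array(white)
  black <- as.array(black)
  if (!identical(dim(white), dim(black))) {
    stop_nirmeat("calibration_refs: white and black must share dimensions")
  }
  structure(list(white = white, black = black), class = "calibration_refs")
}

#' Reflectance calibration of a raw cube
#'
#' Elementwise `I = (I_R - I_B) / (I_W - I_B)`: raw counts minus the dark
#' current, normalised by the dynamic range of the white reference.
#'
#' @param raw an `hsi_cube` of kind `"raw"`.
#' @param refs a [calibration_refs()] with dimensions matching `raw`.
#' @return an `hsi_cube` of kind `"calibrated"`.
#' @export
calibrate <- function(raw, refs) {
  stopifnot(inherits(raw, "hsi_cube"), inherits(refs, "calibration_refs"))
  if (!identical(dim(raw$data), dim(refs$white))) {
    stop_nirmeat("calibrate: reference frames must match the cube dimensions")
  }
  denom <- refs$white - refs$black
  bad <- which(denom == 0)
  if (length(bad)) {
    loc <- arrayInd(bad[1], dim(denom))
    stop_nirmeat(sprintf(
      "calibrate: white == black at %d location(s), first at (row %d, col %d, band %d): division by zero",
      length(bad), loc[1], loc[2], loc[3]))
  }
  if (any(denom < 0)) {
    warning("calibrate: white < black at some locations")
  }
  hsi_cube((raw$data - refs$black) / denom, raw$wavelengths,
           kind = "calibrated")
}

nearest_band <- function(wavelengths, nm) which.min(abs(wavelengths - nm))

#' Parameters of the band-math ROI segmentation
#'
#' The stated workflow is band subtraction + masking to blacken background
#' and shadows, then band addition + binarisation to flag and remove fat and
#' bright spots; the bands and thresholds themselves are configurable here
#' and recorded in the mask provenance. Thresholds default to Otsu's method.
#'
#' @param bg_bands_nm two wavelengths (nm): background removal thresholds
#'   `band(bg_bands_nm[1]) - band(bg_bands_nm[2])`. The default pair sits on
#'   the 1520 nm protein absorption dip and its long-wavelength shoulder:
#'   muscle has a large difference there while the dark backdrop, specular
#'   spots and fat (all spectrally flat) have nearly none, and nearby bands
#'   cancel baseline drift almost exactly.
#' @param fat_bands_nm two wavelengths (nm): fat/bright-spot removal
#'   thresholds `band(fat_bands_nm[1]) + band(fat_bands_nm[2])` inside the
#'   foreground.
#' @param bg_threshold,fat_threshold numeric thresholds; `NULL` means Otsu.
#' @param bg_contrast minimum difference between foreground and background
#'   mean band-difference for the foreground to count as found.
#' @param fat_contrast minimum contrast (reflectance-sum units) between the
#'   flagged bright class and the rest of the ROI before pixels are removed;
#'   prevents Otsu from splitting a clean unimodal ROI.
#' @return list of class `roi_params`.
#' @export
roi_params <- function(bg_bands_nm = c(1700, 1520),
                       fat_bands_nm = c(1250, 1520),
                       bg_threshold = NULL, fat_threshold = NULL,
                       bg_contrast = 0.02, fat_contrast = 0.15) {
  structure(as.list(environment()), class = "roi_params")
}

#' Segment the muscle-only region of interest
#'
#' Stage 1 (background/shadow): threshold the difference image
#' `band_i - band_j`; meat has a distinct band-difference signature while the
#' dark backdrop and flat specular pixels do not. Stage 2 (fat/bright spots):
#' inside the stage-1 mask, threshold the sum image `band_k + band_l` and
#' drop the high class when it is clearly separated.
#'
#' @param cube a calibrated `hsi_cube`.
#' @param params an [roi_params()].
#' @return logical rows x cols mask of class `roi_mask` with attribute
#'   `provenance` (bands, thresholds, pixel counts per stage).
#' @export
segment_roi <- function(cube, params = roi_params()) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(params, "roi_params"))
  if (cube$kind != "calibrated") {
    stop_nirmeat("segment_roi: cube must be calibrated first")
  }
  wl <- cube$wavelengths
  i1 <- nearest_band(wl, params$bg_bands_nm[1])
  i2 <- nearest_band(wl, params$bg_bands_nm[2])
  diff_img <- cube$data[, , i1] - cube$data[, , i2]
  thr_bg <- params$bg_threshold %||% otsu_threshold(diff_img)
  fg <- diff_img > thr_bg
  contrast_bg <- mean(diff_img[fg]) - mean(diff_img[!fg])
  if (!any(fg) || !is.finite(contrast_bg) ||
      contrast_bg < params$bg_contrast) {
    stop_nirmeat("segment_roi: empty ROI (background-removal stage found no foreground)")
  }
  j1 <- nearest_band(wl, params$fat_bands_nm[1])
  j2 <- nearest_band(wl, params$fat_bands_nm[2])
  sum_img <- cube$data[, , j1] + cube$data[, , j2]
  mask <- fg
  thr_fat <- NA_real_
  removed <- 0L
  vals <- sum_img[fg]
  thr_fat <- params$fat_threshold %||% otsu_threshold(vals)
  high <- fg & (sum_img > thr_fat)
  keep <- fg & !high
  if (any(high) && any(keep)) {
    contrast <- mean(sum_img[high]) - mean(sum_img[keep])
    if (contrast >= params$fat_contrast) {
      mask <- keep
      removed <- sum(high)
    }
  }
  if (!any(mask)) {
    stop_nirmeat("segment_roi: empty ROI (fat/bright-spot removal emptied the mask)")
  }
  structure(mask, class = c("roi_mask", class(mask)),
            provenance = list(
              bg_bands = c(i1, i2), bg_bands_nm = wl[c(i1, i2)],
              bg_threshold = thr_bg,
              fat_bands = c(j1, j2), fat_bands_nm = wl[c(j1, j2)],
              fat_threshold = thr_fat,
              n_foreground = sum(fg), n_removed_bright = removed,
              n_final = sum(mask)))
}

#' Extract block-mean spectra from a cube under a mask
#'
#' The masked pixel spectra are randomly permuted (seeded) and partitioned
#' into `k_blocks` near-equal blocks; each block mean becomes one spectrum.
#'
#' @param cube a calibrated `hsi_cube`.
#' @param mask logical rows x cols matrix (e.g. from [segment_roi()]).
#' @param k_blocks number of blocks.
#' @param seed integer seed for the permutation.
#' @param sample_id id recorded in the output metadata.
#' @return a `spectrum_set` with `k_blocks` rows.
#' @export
extract_block_means <- function(cube, mask, k_blocks = 10L, seed = 1L,
                                sample_id = "sample") {
  stopifnot(inherits(cube, "hsi_cube"))
  px <- which(mask)
  if (length(px) < k_blocks) {
    stop_nirmeat(sprintf(
      "extract_block_means: mask has %d pixels, fewer than %d blocks",
      length(px), k_blocks))
  }
  nb <- dim(cube$data)[3]
  flat <- matrix(cube$data, ncol = nb)  # (rows*cols) x bands
  pix <- flat[px, , drop = FALSE]
  blocks <- partition_blocks(nrow(pix), k_blocks, seed = seed)
  mm <- t(vapply(blocks, function(ix) colMeans(pix[ix, , drop = FALSE]),
                 numeric(nb)))
  meta <- data.frame(sample_id = sample_id, block_id = seq_len(k_blocks),
                     block_n = vapply(blocks, length, integer(1)),
                     stringsAsFactors = FALSE)
  spectrum_set(mm, cube$wavelengths, meta,
               processing = list(list(stage = "block_means", k = k_blocks)))
}

#' Crop a spectrum set to a wavelength window
#'
#' Keeps bands with `lo_nm <= wavelength <= hi_nm` (closed interval). The
#' study range drops bands above 2445 nm, where detector noise dominates.
#'
#' @param spectra a `spectrum_set`.
#' @param lo_nm,hi_nm window bounds in nm, `lo_nm < hi_nm`.
#' @return the cropped `spectrum_set`.
#' @export
crop_wavelengths <- function(spectra, lo_nm = 1000, hi_nm = 2445) {
  stopifnot(inherits(spectra, "spectrum_set"))
  if (!(lo_nm < hi_nm)) {
    stop_nirmeat("crop_wavelengths: lo_nm must be < hi_nm")
  }
  keep <- spectra$wavelengths >= lo_nm & spectra$wavelengths <= hi_nm
  if (!any(keep)) stop_nirmeat("crop_wavelengths: no bands in window")
  spectrum_set(spectra$spectra[, keep, drop = FALSE],
               spectra$wavelengths[keep], spectra$meta,
               processing = c(spectra$processing,
                              list(list(stage = "crop",
                                        window = c(lo_nm, hi_nm)))))
}
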