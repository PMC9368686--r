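#' Spectrum collection with sample metadata
#'
#' The working container of the pipeline: an N x B matrix of spectra plus the
#' band wavelength vector and one metadata row per spectrum (sample id, class,
#' pork part, adulteration mass fraction, block/pixel id, set membership).
#'
#' @param spectra numeric matrix, one spectrum per row.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, length `ncol(spectra)`.
#' @param meta `data.frame` with `nrow(spectra)` rows, or `NULL`.
#' @param processing list recording the processing history (methods, stage
#'   order, reference provenance).
#' @return an object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, wavelengths, meta = NULL,
                         processing = list()) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(spectra) != length(wavelengths)) {
    stop_nirmeat("spectrum_set: ncol(spectra) must equal length(wavelengths)")
  }
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    stop_nirmeat("spectrum_set: wavelengths must be strictly increasing")
  }
  if (is.null(meta)) {
    meta <- data.frame(spectrum = seq_len(nrow(spectra)))
  }
  if (nrow(meta) != nrow(spectra)) {
    stop_nirmeat("spectrum_set: meta must have one row per spectrum")
  }
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 processing = processing),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d bands (%.1f-%.1f nm)\n",
              nrow(x$spectra), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (length(x$processing)) {
    cat("  processing:", paste(vapply(x$processing, function(p)
      if (is.list(p)) p$stage %||% "?" else as.character(p), ""),
      collapse = " -> "), "\n")
  }
  cols <- setdiff(names(x$meta), "spectrum")
  if (length(cols)) cat("  meta:", paste(cols, collapse = ", "), "\n")
  invisible(x)
}

#' Row-subset a spectrum set
#'
#' @param x a `spectrum_set`.
#' @param i row index (logical or integer).
#' @return a `spectrum_set` with the selected spectra and metadata rows.
#' @export
subset_spectra <- function(x, i) {
  stopifnot(inherits(x, "spectrum_set"))
  spectrum_set(x$spectra[i, , drop = FALSE], x$wavelengths,
               x$meta[i, , drop = FALSE], x$processing)
}

#' @export
dim.spectrum_set <- function(x) dim(x$spectra)

#' Write / read a spectrum set as plain CSV
#'
#' Column layout: the metadata columns first, then one column per wavelength
#' named `wl_<nm>`.
#'
#' @param x a `spectrum_set`.
#' @param path CSV file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a `spectrum_set`.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectrum_set"))
  wl_cols <- sprintf("wl_%.10g", x$wavelengths)
  mat <- as.data.frame(x$spectra)
  names(mat) <- wl_cols
  utils::write.csv(cbind(x$meta, mat), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  is_wl <- grepl("^wl_", names(df))
  if (!any(is_wl)) stop_nirmeat("read_spectra_csv: no wl_* columns found")
  wl <- as.numeric(sub("^wl_", "", names(df)[is_wl]))
  spectrum_set(as.matrix(df[, is_wl, drop = FALSE]), wl,
               df[, !is_wl, drop = FALSE])
}
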