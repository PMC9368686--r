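#' Write a cube in ENVI band-sequential layout
#'
#' Produces `<base>.dat` (float32, BSQ, little-endian, band-major with
#' row-major planes) and an ASCII `<base>.hdr` carrying the image dimensions
#' and the wavelength list, readable by standard ENVI-compatible software.
#'
#' @param cube an `hsi_cube`.
#' @param base path prefix without extension.
#' @return `base`, invisibly.
#' @export
write_envi <- function(cube, base) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  hdr <- c("ENVI",
           "description = {nirmeat export}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = nm",
           paste0("wavelength = {",
                  paste(sprintf("%.6f", cube$wavelengths), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    # BSQ plane is row-major (samples fastest): transpose the R column-major
    plane <- t(cube$data[, , b])
    writeBin(as.numeric(plane), con, size = 4L, endian = "little")
  }
  invisible(base)
}

#' Read an ENVI band-sequential cube
#'
#' Supports the subset of the ENVI header this package writes: BSQ interleave,
#' data type 4 (float32) or 5 (float64), byte order 0.
#'
#' @param base path prefix without extension (expects `.hdr` and `.dat`).
#' @param kind cube kind to stamp on the result.
#' @return an `hsi_cube`.
#' @export
read_envi <- function(base, kind = "calibrated") {
  hdr_path <- paste0(base, ".hdr")
  if (!file.exists(hdr_path)) stop_nirmeat("read_envi: missing ", hdr_path)
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*(\\d+)"), txt))[[1]]
    if (length(m) < 2L) stop_nirmeat("read_envi: header lacks ", key)
    as.integer(m[2])
  }
  samples <- get_num("samples")
  lines_n <- get_num("lines")
  bands <- get_num("bands")
  dtype <- get_num("data type")
  if (!dtype %in% c(4L, 5L)) {
    stop_nirmeat("read_envi: unsupported data type ", dtype)
  }
  il <- regmatches(txt, regexec("interleave\\s*=\\s*(\\w+)", txt))[[1]][2]
  if (!identical(tolower(il), "bsq")) {
    stop_nirmeat("read_envi: only bsq interleave is supported")
  }
  wl_m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(wl_m) < 2L) stop_nirmeat("read_envi: header lacks wavelengths")
  wl <- as.numeric(strsplit(wl_m[2], ",")[[1]])
  if (length(wl) != bands) {
    stop_nirmeat("read_envi: wavelength list length != bands")
  }
  size <- if (dtype == 4L) 4L else 8L
  con <- file(paste0(base, ".dat"), "rb")
  on.exit(close(con))
  arr <- array(0, dim = c(lines_n, samples, bands))
  for (b in seq_len(bands)) {
    plane <- readBin(con, "numeric", n = samples * lines_n, size = size,
                     endian = "little")
    arr[, , b] <- t(matrix(plane, samples, lines_n))
  }
  hsi_cube(arr, wl, kind = kind)
}
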