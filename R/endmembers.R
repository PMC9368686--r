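#' Endmember spectral model for mutton and essence-treated pork
#'
#' Parametrises the pure-meat reflectance spectra that the generator mixes.
#' Absorbance is modelled as a smooth class baseline plus Gaussian absorption
#' dips at the four NIR features characteristic of minced meat (N-H first and
#' second overtones near 1020 and 1520 nm, C-H second overtone near 1250 nm,
#' the O-H combination band of water near 2150 nm); reflectance is
#' `10^(-absorbance)`. Mutton and pork share peak positions but differ in dip
#' amplitude and baseline, so their spectra follow the same trend at clearly
#' distinct reflectance levels. Essence treatment is a small additive
#' absorbance perturbation of the pork endmember.
#'
#' @param wavelengths band centres in nm, strictly increasing (default 288
#'   equally spaced points on 1000-2500 nm).
#' @param peak_centers absorption-dip centres in nm.
#' @param peak_widths Gaussian dip standard deviations in nm.
#' @param peak_amplitudes list with numeric vectors `mutton` and `pork`
#'   (absorbance units, one value per peak).
#' @param baseline list with `mutton` and `pork` vectors `c(intercept, slope)`
#'   of the linear absorbance baseline over the normalised wavelength axis.
#' @param essence_shift additive absorbance applied to the pork endmember to
#'   represent the flavour essence (a configurable stand-in, not an estimate
#'   of real essence chemistry).
#' @return object of class `endmember_model`.
#' @export
endmember_model <- function(
    wavelengths = seq(1000, 2500, length.out = 288),
    peak_centers = c(1020, 1250, 1520, 2150),
    peak_widths = c(30, 50, 55, 70),
    peak_amplitudes = list(mutton = c(0.10, 0.16, 0.14, 0.22),
                           pork   = c(0.15, 0.24, 0.20, 0.30)),
    baseline = list(mutton = c(0.22, 0.10), pork = c(0.30, 0.14)),
    essence_shift = 0.02 * mean(peak_amplitudes$pork)) {
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) {
    stop_nirmeat("endmember_model: wavelengths must be strictly increasing")
  }
  np <- length(peak_centers)
  if (length(peak_widths) != np ||
      length(peak_amplitudes$mutton) != np ||
      length(peak_amplitudes$pork) != np) {
    stop_nirmeat("endmember_model: peak widths/amplitudes must match centers")
  }
  if (any(peak_widths <= 0)) stop_nirmeat("endmember_model: widths must be > 0")
  if (any(unlist(peak_amplitudes) < 0)) {
    stop_nirmeat("endmember_model: amplitudes must be >= 0")
  }
  m <- structure(list(wavelengths = wavelengths, peak_centers = peak_centers,
                      peak_widths = peak_widths,
                      peak_amplitudes = peak_amplitudes,
                      baseline = baseline, essence_shift = essence_shift),
                 class = "endmember_model")
  for (cl in c("mutton", "pork", "pork_essence")) {
    r <- generate_endmembers(m, cl)
    if (any(r <= 0) || any(r > 1)) {
      stop_nirmeat("endmember_model: generated reflectance must lie in (0, 1]")
    }
  }
  m
}

#' Generate one endmember reflectance spectrum
#'
#' @param model an [endmember_model()].
#' @param class_label one of `"mutton"`, `"pork"`, `"pork_essence"`.
#' @return reflectance vector over `model$wavelengths`.
#' @export
generate_endmembers <- function(model, class_label) {
  stopifnot(inherits(model, "endmember_model"))
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% c("mutton", "pork", "pork_essence")) {
    stop_nirmeat("generate_endmembers: class_label must be one of ",
                 "\"mutton\", \"pork\", \"pork_essence\"")
  }
  base_cl <- if (class_label == "mutton") "mutton" else "pork"
  wl <- model$wavelengths
  u <- (wl - min(wl)) / max(diff(range(wl)), 1)
  b <- model$baseline[[base_cl]]
  absorb <- b[1] + b[2] * u
  amps <- model$peak_amplitudes[[base_cl]]
  for (k in seq_along(model$peak_centers)) {
    absorb <- absorb + amps[k] *
      exp(-0.5 * ((wl - model$peak_centers[k]) / model$peak_widths[k])^2)
  }
  if (class_label == "pork_essence") absorb <- absorb + model$essence_shift
  10^(-absorb)
}

#' Mix two endmember spectra at a pork mass fraction
#'
#' Linear mixing in absorbance (a Beer-Lambert surrogate): both reflectance
#' spectra are converted to absorbance `-log10(R)`, combined as
#' `p * pork + (1 - p) * mutton`, and converted back.
#'
#' @param p pork mass fraction in `[0, 1]` (g/g).
#' @param mutton_spec,pork_spec reflectance vectors on a common band grid.
#' @return mixed reflectance spectrum.
#' @export
mix_spectrum <- function(p, mutton_spec, pork_spec) {
  check_number(p, "p", 0, 1)
  if (length(mutton_spec) != length(pork_spec)) {
    stop_nirmeat("mix_spectrum: endmember spectra must share the band grid")
  }
  if (any(mutton_spec <= 0) || any(pork_spec <= 0)) {
    stop_nirmeat("mix_spectrum: reflectance must be positive")
  }
  if (p == 0) return(mutton_spec)
  if (p == 1) return(pork_spec)
  10^(p * log10(pork_spec) + (1 - p) * log10(mutton_spec))
}
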