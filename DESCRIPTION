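Package: nirmeat
Title: NIR Hyperspectral Chemometrics for Meat Adulteration Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Classification and quantification of mutton adulterated with
    flavour-essence-treated pork from near-infrared hyperspectral images
    (288 bands, 1000-2500 nm). Provides a synthetic spectrum and cube
    generator emulating the sampling design of an adulteration study,
    white/black reference reflectance calibration, band-math region-of-
    interest segmentation with block-mean spectral extraction, first
    derivative plus multiplicative scatter correction preprocessing, and
    three-class discrimination / mass-fraction regression with back
    propagation networks, extreme learning machines and support vector
    machines, each optionally tuned by the sparrow search algorithm with
    grouped cross-validated fitness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    MASS,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
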