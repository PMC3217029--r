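Package: chromoscale
Title: Reconstruct Structural Colors from Scale Nanostructure Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the structural colors produced by
    multilayer (thin-film) reflectors in lepidopteran wing scales from
    cross-section electron micrographs. A grayscale micrograph is segmented
    into a two-phase chitin/air refractive-index map, analyzed by 2-D discrete
    Fourier transform, radially averaged to a power profile over spatial
    frequency, and mapped to a predicted normal-incidence reflectance spectrum
    whose peak wavelength is converted to RGB color. Includes a synthetic
    nanostructure image generator with closed-form ground truth, closed-form
    multilayer and transfer-matrix optics oracles, diffraction-order counting,
    lamina perforation morphometrics, and utilities for normalizing and
    peak-finding measured reflectance spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    data.table,
    jsonlite,
    yaml,
    png,
    tiff,
    withr,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
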