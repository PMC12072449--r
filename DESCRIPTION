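Package: adductscreen
Title: Nucleoside Adduct Stability Screening for Post-Column Addition LC-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening small molecules (in particular plant
    phenolics) for their affinity toward 2'-deoxyguanosine and guanosine by
    post-column addition liquid chromatography-mass spectrometry, a proxy for
    G-quadruplex binding. Provides molecular-formula algebra and adduct m/z
    calculation, conversion of cone-voltage (laboratory) collision energies to
    degrees-of-freedom-corrected center-of-mass energies, extracted-ion
    chromatogram integration, adduct survival-ratio curves with sigmoid
    midpoint fits, compound ranking, and a synthetic LC-MS run generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
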