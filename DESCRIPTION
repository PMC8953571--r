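Package: stabindr
Title: Stability-Indicating Assay Analytics for Drug Degradation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational companion to stability-indicating HPLC-DAD /
    LC-ESI-QTOF-MS drug degradation studies. Provides degradation-kinetics
    model selection across zero-, first- and second-order rate laws with
    half-life (t1/2) and shelf-life (t90) estimation, ICH Q2 method-validation
    statistics (linearity, LLOD/LLOQ, recovery, precision, percent
    degradation), chromatographic system-suitability metrics (plate count,
    asymmetry factor, capacity factor) from sampled traces, monoisotopic-mass
    arithmetic with elemental-composition assignment of high-resolution
    fragment ions at ppm accuracy, and seeded synthetic-data generators that
    emulate detector response, decay time-courses, tailing chromatographic
    peaks and mass-jittered fragment spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
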