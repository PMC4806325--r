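Package: radrepro
Title: Test-Retest Reproducibility of CT Radiomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An 89-feature CT radiomics engine (15 feature classes spanning size,
    shape, surface shape, margin sharpness, first-order density statistics and
    texture), a test-retest concordance analysis built on Lin's concordance
    correlation coefficient with Dixon's Q outlier screening, cut-off summary
    tables and heat-map export, and a seeded synthetic CT tumor-phantom
    generator that emulates same-day repeat scans reconstructed at three slice
    thicknesses under sharp and smooth reconstruction kernels, so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
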