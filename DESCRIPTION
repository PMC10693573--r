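Package: vped
Title: Virtual Pathology Endometrial Dating from Tissue-Element Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating the menstrual cycle day from magnified images of
    the endometrial surface ("virtual pathology"). The package segments gland
    outlets (pores) and blood vessels on brightfield-style images, computes
    per-element morphometric features and global tissue attributes, models
    feature ensembles with three-parameter Weibull cumulative distribution
    functions, and infers the cycle day by Kolmogorov-Smirnov matching against
    a per-day reference dictionary. Traditional reference datings (chi-square
    hormone dating, cycle renormalization, histology and patient-report
    ingestion) and concordance analysis between methods are included, together
    with a synthetic tissue and cohort generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    EBImage
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
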