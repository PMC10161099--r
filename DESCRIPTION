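Package: colloidquant
Title: Quantification of Colloidal Drug Aggregate Uptake and
    Endo-Lysosomal Disruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for high-content imaging studies of
    ionizable colloidal drug aggregates. Quantifies multi-channel
    fluorescence micrographs (cell nuclei, galectin-8 endosomal-disruption
    foci, lipid-dye colloid puncta, and phospholipidosis vesicles) via
    top-hat background removal, thresholding, and watershed splitting;
    fits apparent-pKa titration curves from TNS assays and mono- or
    biphasic dose-response curves; and decomposes endo-lysosomal
    disruption into colloid-mediated (regression slope) and
    free-drug-mediated (intercept) components, with cross-compound
    correlation against phospholipidosis. A synthetic-data module
    generates micrographs with known ground truth, titration and
    dose-response curves, and two-mechanism well panels so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
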