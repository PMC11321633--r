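Package: mictrack
Title: Tracking and Scoring Metastasis-Initiating Cells Across Metastatic Timepoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and scoring machinery for metastasis-initiating
    cells (MICs) in multi-timepoint single-cell experiments. Provides a
    negative-binomial single-cell count simulator with planted MIC
    subpopulations and dropout control, the boolean "1+1" marker
    co-expression classifier with closed-form and empirical confusion-matrix
    evaluation, epithelial-mesenchymal state assignment from marker
    positivity fractions, metastatic colony-size classification, and a
    clinical differential-signature score (dMISs) with survival-based
    cutpoint selection and outcome-association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
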