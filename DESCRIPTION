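Package: hwdensity
Title: Hydrostatic Weighing Densitometry and Method-Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete analysis pipeline for hydrostatic (underwater)
    weighing of human body composition. Quality-controls repeated head and
    face girth measurements, predicts head volume and lung volumes (total
    lung capacity and residual volume) from anthropometry, selects
    consistent in-water weighing trials, inverts Archimedes' principle to
    condition-specific body density, and converts density to percent body
    fat via the Brozek transform. Supports three weighing conditions (head
    above water at total lung capacity, head below water at total lung
    capacity, head below water at residual volume) and compares them with
    paired t-tests, Bland-Altman limits of agreement, proportional-bias
    regression, and Lin's concordance correlation coefficient. Includes a
    synthetic-cohort generator that forward-simulates girths and in-water
    weights from known ground truth so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
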