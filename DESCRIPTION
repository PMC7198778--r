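Package: n2opart
Title: Partitioning Gross N2O Production and Consumption from
    Acetylene-Inhibition Soil Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for soil microcosm studies that partition net
    nitrous oxide (N2O) emission into gross production and gross consumption
    using the acetylene (C2H2) inhibition design (0 Pa / 10 Pa / 10 kPa
    headspace treatments). Converts paired headspace concentrations to net
    flux rates per gram dry soil, estimates gross process rates with
    replicate-paired or propagated standard errors, quantifies uncertainty by
    case bootstrap combined with Monte-Carlo measurement noise, fits van't
    Hoff temperature-response curves to obtain Q10 temperature sensitivities,
    and relates process rates to N2O-reducer community traits via T-RFLP
    profile processing, Bray-Curtis dissimilarity, permutation Mantel tests,
    PERMANOVA and qPCR standard-curve quantification. Ships a calibrated
    synthetic microcosm-study generator so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
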