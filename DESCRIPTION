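Package: allonet
Title: Functional Mapping of Height-Diameter Allometry QTLs and
    ODE-Based QTL Control Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps "pioneering" and "maintaining" allometry QTLs from
    longitudinal shoot height and diameter measurements in full-sib
    families via functional mapping with bidirectional height-diameter
    allometry equations and an AR(1)-structured multivariate-normal
    likelihood, and reconstructs signed, weighted, directed QTL-QTL
    control networks by decomposing each QTL's genetic-effect curve
    into independent and regulator-dependent components through a
    system of ordinary differential equations with sparse regulator
    selection. Includes a synthetic mapping-population generator, a
    14-QTL network simulator, and a simulation study scoring directed
    edge recovery (TP, FP, TPR, FPR, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
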