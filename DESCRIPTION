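Package: pedpart
Title: Partitioning Breeding Values and Genetic Trends by Selection Path
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Partitions breeding values into parent-average and Mendelian
    sampling terms and attributes them to user-defined selection paths
    (gender, population, tier), yielding partial genetic trends that
    quantify the realised contribution of each path to genetic gain.
    Includes pedigree pre-processing utilities (birth-year imputation,
    pedigree rebasing, topological sorting), a sparse gene-flow-matrix
    route used for cross-checking the recursive partitioning, result
    summarisation and manipulation (subsetting and combining paths),
    trend plotting, a single-trait pedigree BLUP solver, and stochastic
    simulators of breeding programmes (a three-population import scenario
    and a two-tier nucleus/multiplier programme) for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
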