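Package: bacfilter
Title: Carbon Mass-Balance Analysis of Biological Activated Carbon Filters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Long-term total organic carbon (TOC) mass-balance analysis for
    biological activated carbon (BAC) filters used in greywater post-treatment.
    Partitions removed TOC into sorption and biodegradation from an equilibrium
    sorption loading (q_e), partitions biodegraded carbon into CO2 and
    assimilated biomass (accumulated on the medium, washed out, removed by
    backwash) using ATP and flow-cytometric cell-count conversions, fits a
    depth-resolved linear model of the removal ratio against operating time,
    influent TOC and empty bed contact time, and ships a mechanistic
    intermittent-flow tanks-in-series column simulator with known ground truth
    for validating the estimation pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
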