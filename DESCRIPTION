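Package: guildcom
Title: Guild-Level Community Metabolic Modeling of Microbial Fuel Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles guild-level genome-scale metabolic models into a
    compartmentalized community model with a shared metabolite pool, solves
    the SteadyCom community growth problem (maximal common growth rate under
    abundance-scaled capacity bounds), derives condition-specific community
    exchange constraints from wastewater chemistry (COD, volatile fatty
    acids, sulfate, sulfide), fits guild exchange capacities to observed
    relative abundances, and runs flux fold-change analytics and sensitivity
    scans (organic loading sweeps, two-dimensional capacity scans, proton
    sweeps). Includes a fully specified synthetic three-guild community
    (sulfate reducers, acetoclastic methanogens, sulfide oxidizers) so the
    whole pipeline is testable without external model files, plus SBML
    import/export for constraint-based models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    xml2,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
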