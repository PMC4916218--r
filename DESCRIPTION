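Package: lipid2h
Title: Compound-Specific Hydrogen Isotope Data Reduction for Microbial Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data reduction and analysis for compound-specific hydrogen
    isotope (2H/1H) measurements of microbial fatty acids by GC-irMS.
    Converts raw per-injection fatty acid methyl ester (FAME) delta-2H
    values to free-acid values on the V-SMOW scale via coinjected-standard
    referencing and methyl-group mass-balance correction, applies
    bracketing-standard quality control, aggregates pseudoreplicate
    injections with propagated errors, and computes per-lipid and
    pool-weighted apparent fractionations against growth-medium water.
    Also fits modified-logistic growth curves to OD600 time series with
    diauxic-phase detection and biomass-weighted average growth rates,
    quantifies lipid profiles against an internal standard, computes Kovats
    retention indices, screens Pearson correlations, fits growth-rate
    versus fractionation models, and performs branched-chain primer
    mass-balance inference. A seeded synthetic-study generator emulates a
    complete experiment so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
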