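Package: gasferm
Title: Stoichiometric Energy-Conservation Analysis of Acetogenic Gas Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cofactor-balanced stoichiometric analysis of Clostridium
    ljungdahlii gas fermentation. Encodes the central Wood-Ljungdahl
    metabolism as an exact-rational metabolic network, solves steady-state
    flux distributions for CO and H2/CO2 feed schemes, and tallies net ATP
    yields from substrate-level phosphorylation plus Rnf/ATP-synthase
    chemiosmosis. Includes transformed Gibbs-energy bookkeeping for the net
    fermentation equations, end-product molar-ratio analysis, an
    RPKM-threshold transcript screen, and a synthetic bioreactor time-course
    generator for testing the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
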