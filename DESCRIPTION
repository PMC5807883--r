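Package: caulipheno
Title: Genome-Based Phenology Modelling of Curd Induction in Cauliflower
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated quantitative-genetics and phenology modelling for time
    to curd induction in cauliflower (Brassica oleracea var. botrytis).
    Estimates per-genotype thermal-time response parameters (leaf appearance
    rate, temperature sensitivity and minimum adult-phase thermal time) from
    multi-temperature trials, maps QTL for those parameters by composite
    interval mapping, fits genome-wide marker effects by ridge-regression
    BLUP, and drives a two-phase development simulator with genome-predicted
    parameters to forecast day of curd induction under arbitrary daily
    temperature series. Includes a calibrated doubled-haploid population and
    trial simulator for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
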