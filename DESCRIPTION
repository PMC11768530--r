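Package: modprox
Title: Disease-Module Detection and Network-Proximity Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds heterogeneous metabolite-protein background networks,
    derives node scores from two-group differential omics (metabolite and
    transcript layers), grows score-weighted disease modules by stochastic
    seed expansion with a hypergeometric connectivity-significance test,
    condenses a module ensemble into a consensus disease module, and ranks
    drugs by closest-distance network proximity normalized against a
    degree-preserving permutation null. Includes a seeded synthetic-data
    generator (scale-free background with a planted module, programmed
    fold changes, and drug libraries at controlled distance) so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
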