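Package: tdmdtools
Title: Screening and Quantification of Target-Directed microRNA Degradation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying target-directed microRNA degradation (TDMD)
    in transcriptomic data: candidate-target screening from 3'-complementarity
    (3C) score tables, miRNA:target duplex anatomy (seed class, central bulge,
    3' supplementary pairing) and TDMD eligibility rules, isomiR
    tailing/trimming profiling from small-RNA reads, absolute stoichiometry
    (standard curves, copies per cell, target-per-miRNA ratios), miRNA
    activity and de-repression statistics, CRISPR deletion arithmetic for
    miRNA responsive elements, and seed-reproducible synthetic-data
    generators, including a saturable TDMD kinetics simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
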