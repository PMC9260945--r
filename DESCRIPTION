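Package: ipscreen
Title: In Silico Screening Toolkit for an Imidazo[1,2-a]pyridine Compound
    Library
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for the computational triage of a small
    imidazo[1,2-a]pyridine compound library: structure-derived
    physicochemical descriptors and Lipinski rule-of-five verdicts,
    conceptual-DFT global reactivity indices (Koopmans/Parr) from frontier
    orbital energies, condensed Fukui functions from per-atom charges at
    three electron counts, docking-score ranking and selectivity summaries
    over per-target score tables, and ADMET/TOPKAT level and probability
    banding. Includes a seeded synthetic-data generator with planted
    ground truths so every stage is testable without external engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
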