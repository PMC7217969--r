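Package: netsl
Title: Network Meta-Analysis and Context-Dependence Ranking of Synthetic
    Lethal Screens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating independent synthetic-lethal RNAi screens
    on a protein-interaction network. Detects pathway-level convergence of
    screens via permutation statistics on cross-study network connectivity,
    nominates candidate genes by dense-module (MCODE-style) discovery with
    gene-set enrichment, scores isogenic single-gene and combinatorial
    (E-MAP) knockdown screens across growth conditions, and ranks candidates
    by a composite context-independence score combining condition-to-condition
    score variance and genetic-suppressor burden. A seeded synthetic-data
    generator emulates every input so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
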