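Package: netpharm
Title: Network Pharmacology Analysis of Herbal Component-Target-Pathway Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, reproducible network-pharmacology toolkit for
    multi-component herbal medicines. Screens herb components by ADME
    criteria (oral bioavailability, Caco-2 permeability, Tanimoto
    drug-likeness, gastrointestinal absorption class and Lipinski's rule
    of five), aggregates per-source component-target associations into a
    bipartite component-target network with degree statistics, filters
    STRING-dialect protein-protein interaction tables at a confidence
    cutoff, intersects herb and disease target sets, detects dense
    modules with an MCODE-style seed-and-grow k-core clustering
    (density x size scoring), performs hypergeometric over-representation
    analysis of gene-set collections with Benjamini-Hochberg adjustment,
    and assembles component-target-pathway networks for export. Includes
    seeded synthetic-data generators (property tables, planted-clique
    graphs, gene-set collections) so every stage is testable without
    database access, and a config-driven pipeline runner with a run
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
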