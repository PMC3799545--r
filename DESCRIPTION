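Package: xspheno
Title: Construction of a Cross-Species Phenotype Ontology from Entity-Quality Definitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a single cross-species (human, mouse, zebrafish) phenotype
    ontology from OBO building-block ontologies, Entity-Quality (EQ) logical
    definitions and Uberon bridging axioms, using a structural subsumption
    reasoner over the EQ fragment. Synthesizes pre-composed zebrafish
    phenotype (ZP) classes from post-composed ZFIN-style annotations, merges
    clusters of equivalent classes under a primary identifier with alt_id
    bookkeeping, exports the merged ontology in OBO format, and propagates
    model-organism phenotype annotations to human genes via orthology.
    Includes a deterministic synthetic-fixture generator and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
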