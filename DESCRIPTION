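Package: snp2drug
Title: Genomics-Driven Drug Repurposing by Functional Annotation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes disease risk genes from SNP-level functional
    annotation snapshots and identifies drug repurposing candidates.
    Five binary annotation categories (missense variant, whole-blood
    cis-eQTL, pathway enrichment, gene-ontology biological-process
    enrichment, and knockout-mouse phenotype enrichment) are scored per
    gene; genes scoring at least 2 are called risk genes, expanded
    through a weighted protein-protein interaction network, joined
    against a drug-target table, and triaged by clinical or preclinical
    evidence into drugs already in development versus novel repurposing
    candidates. Includes a synthetic-data generator with planted signal
    for end-to-end validation and packaged reference tables from a
    depression case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
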