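Package: mirhub
Title: Multi-Database miRNA Target Evidence Integration, Hub Selection and
    GO Over-Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates miRNA-mRNA interaction evidence from two predicted
    databases (miRDB-style target scores, microRNA.org-style mirSVR scores)
    and one experimentally validated database (miRTarBase-style), applies
    per-database quality filters, scores each (miRNA, gene) pair with a
    compound evidence score (0.5 points per supporting predicted database,
    1 point for validated support), retains pairs scoring at least 1, builds
    a bipartite miRNA-target network over differentially expressed miRNAs,
    selects hub mRNAs by interaction degree, and tests target sets for gene
    ontology over-representation with Bonferroni correction. A seeded
    synthetic-data generator with planted hubs, excluded miRNAs and enriched
    terms makes every stage testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
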