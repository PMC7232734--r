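Package: coexatlas
Title: Cross-Tissue Weighted Gene Coexpression Networks and Module Overlap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene coexpression networks per tissue (absolute
    Pearson similarity, soft-threshold power adjacency, topological overlap),
    detects modules by average-linkage hierarchical clustering with a
    tree-shape-based dynamic branch cut, compares modules across tissues with
    one-sided Fisher exact overlap tests, extracts the maximum clique of
    mutually overlapping modules, and performs hypergeometric gene-set
    enrichment against a GMT collection. Includes a synthetic multi-tissue
    expression generator with planted modules providing ground truth for the
    whole pipeline, and an end-to-end pipeline driver with deterministic
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
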