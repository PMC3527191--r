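Package: mycostarve
Title: Hyphal Morphometry, Differential Expression and Ontology
    Summarization for Carbon-Starved Mycelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the morphological and transcriptional
    response of filamentous fungi to carbon starvation. Implements
    skeleton-based hyphal diameter morphometry from stained micrographs
    (binarization, outlining, skeletonization, junction pruning,
    fragment-wise orthogonal width measurement and kernel density
    summaries of thin/thick hyphal populations), empirical-Bayes
    moderated t-tests for starvation versus exponential-growth
    contrasts with three-way Venn logic, Fisher's exact enrichment of
    ontology, domain or pathway annotations with Benjamini-Hochberg
    control, and a DAG-based reduction of enriched Gene Ontology terms
    to common most-specific terms across time points. Ground-truthed
    synthetic generators for micrographs, ontologies, annotations and
    expression matrices make every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    igraph,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
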