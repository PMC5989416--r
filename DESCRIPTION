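Package: mgogp
Title: Module and Gene Ontology Based Disease Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease genes by combining the importance of
    gene modules with the importance of genes inside them. Module importance
    is scored from consensus differential expression (repeated stratified
    subsampling with a vote threshold), consensus differential correlation
    (Fisher z-tests on condition-specific Pearson correlations, thresholded
    on a local false discovery rate), and the number of known disease genes
    in the module. Gene importance adds a Gene Ontology semantic similarity
    to known disease genes built on a Sugeno lambda fuzzy measure over
    normalized information content of GO terms. Per-module gene rankings are
    fused into one global ranking by an expectation-driven recursion. Ships
    readers for expression TSV, GMT gene sets, OBO ontologies, GAF or
    two-column annotations, and a deterministic synthetic-fixture generator
    with planted signal for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
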