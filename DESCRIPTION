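Package: hypercoev
Title: Hyperedge Co-Evolution Analysis of Dynamic Functional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds time-resolved functional connectivity networks from
    region-level signal, extracts edge-weight time series over non-overlapping
    windows, and groups edges whose weights co-evolve into hyperedges: connected
    components of the FDR-thresholded, binarized edge-edge correlation matrix.
    Includes hypergraph diagnostics (size distributions, hyperedge node degree,
    co-evolution probability networks), permutation tests for task-specific
    hyperedges, length-strength and position-strength spatial metrics, overall
    and within-task null models, a coefficient-of-variation driven hybrid-atlas
    refinement, and a synthetic-data generator with planted co-evolution
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
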