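Package: qnscreen
Title: Qualitative Network Modeling and In Silico Inhibitor Screening of
    Clonally Heterogeneous Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An executable-biology toolkit for qualitative networks (QNs), the
    multi-valued generalization of Boolean networks in which each node carries a
    bounded integer activity level and moves stepwise toward a real-valued target
    function of its regulators. Provides a BMA-compatible JSON model dialect with
    a target-function formula parser, deterministic synchronous simulation,
    exhaustive attractor enumeration, and sound interval-narrowing stability
    analysis. Ships a curated Myc/Ras/p53/Wnt/HIF signaling model of biclonal
    (Myc-high/Myc-low) Wnt-driven breast tumors together with clone
    configurations, a qualitative-expectation validation harness, and an
    exhaustive single and pairwise in-silico inhibitor screen with healthy-cell
    toxicity filtering and add-a-second-inhibitor delta matrices, recovering the
    clonal-mutualism and MEK+COX2 combination-therapy predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
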