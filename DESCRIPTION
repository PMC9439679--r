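Package: loopdelta
Title: Differential Chromatin Architecture Analysis for Two-Condition Hi-C
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing chromatin architecture between two
    conditions from binned Hi-C contact matrices: iterative-correction
    balancing, A/B compartment eigenvector tracks with switch
    classification, diamond insulation scores with TAD boundary calling
    and aggregate-TAD maps, spline-prior binomial loop calling with
    Benjamini-Hochberg correction and common/group-specific differential
    classification, and integration of promoter-anchored loops with
    differential-expression classes and ChIP peak occupancy, including
    dot- and TSS-centred pile-ups with central-pixel enrichment and
    promoter-stripe scoring. A synthetic-data module generates
    two-condition contact maps with planted compartments, TADs, loops and
    stripes plus matched gene and peak tables, so the whole pipeline is
    testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
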