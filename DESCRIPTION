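Package: subnetr
Title: Individual-Specific Functional Subnetwork Detection, Matching, and
    Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mapping fine-scale community structure in dense
    functional-connectivity matrices from individual subjects, matching the
    resulting subnetworks across subjects by spatial overlap, annotating
    distributed subnetworks against a coordinate-based meta-analytic database,
    profiling subnetwork-to-network connectivity and task activation with
    repeated-measures statistics, and estimating the temporal ordering of
    infraslow subnetwork signals via lagged cross-covariance. Includes a
    synthetic-data generator with planted ground truth so the full pipeline is
    testable without neuroimaging downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
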