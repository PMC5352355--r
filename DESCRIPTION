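Package: alkscreen
Title: Three-Level qPCR Calling of ALK Rearrangements with Microarray
    Marker Discovery
Version: 0.4.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening non-small-cell lung cancer samples for ALK
    rearrangements from quantitative PCR data. Implements the marker-discovery
    path used on Affymetrix expression arrays (quantile normalization, Tukey
    median-polish probe-set summarization, SAM two-class permutation statistics
    with permutation-based FDR, linear fold change, and one-mismatch probe to
    transcript matching), a three-level ALK caller built on cycle-threshold
    tables (marker delta-Ct against HPRT1/ESD reference genes, 5'/3' ALK
    transcript imbalance, and a fusion-subtype primer panel with melt-curve
    gating), simulators for break-apart FISH and binary IHC reference assays
    driven by tumor-cell fraction, and a synthetic cohort generator so the
    whole pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
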