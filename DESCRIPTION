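Package: ednassay
Title: Design and Evaluation of Species-Specific eDNA PCR Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and evaluating species-specific
    environmental DNA (eDNA) detection assays from whole-mitogenome
    alignments. Scans target versus non-target alignments for
    diagnostic windows, designs conventional and hydrolysis-probe
    (TaqMan) qPCR candidates under amplicon-length and melting
    temperature constraints, screens candidates by mismatch-tolerant
    in-silico PCR on linear or circular templates, fits qPCR standard
    curves for plasmid-based copy-number estimation, and summarises
    replicate-level detection data: positive calls, dilution-series
    sensitivity and limits of detection, per-marker detection rates,
    and multi-marker union/complementarity analysis. Includes seeded
    generators for synthetic mitogenome panels and qPCR runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
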