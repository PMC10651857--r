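Package: splicefx
Title: Functional Consequences of Alternative Splicing Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of event-based alternative splicing
    detections. Takes per-event exon coordinates and per-sample isoform
    read counts, filters events (missingness, percent-spliced-in
    variability, protein-coding genes), tests for differential splicing
    with a two-group beta-binomial model of PSI with group-specific
    overdispersion, predicts the reading frame of each event from its
    first 5' exon (single open reading frame and peptide matching to
    known proteins, with a full-isoform fallback), translates both
    isoforms, decomposes protein-level differences (shared and altered
    peptides, stop codons, frameshifts), and renders event, transcript
    and protein-domain visualizations. Includes a deterministic
    synthetic-data generator so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ggplot2,
    patchwork,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
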