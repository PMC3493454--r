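Package: nucenrich
Title: Spectral-Count Enrichment Discovery for Nucleosome
    Affinity-Purification Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for candidate discovery in
    affinity-purification mass spectrometry of nucleosomes: target/decoy
    false-discovery-rate filtering of peptide-spectrum matches, parsimony
    protein grouping with a two-unique-peptide rule, razor spectral
    counting, and a replicate-aware two-stage fold-enrichment cascade that
    compares a histone-variant bait (e.g. H2A.Z) against a tag-only
    control (GFP) and a canonical-histone comparator (H2A). Includes a
    ground-truthed synthetic peptide-spectrum-match generator so every
    stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
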