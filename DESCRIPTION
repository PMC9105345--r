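Package: nonbdna
Title: Non-B DNA Motif Detection and Regulatory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of the seven classical non-B DNA motif classes
    (G-quadruplexes, Z-DNA, inverted/direct/mirror repeats, short tandem
    repeats and H-DNA) in DNA sequence, with full substructure reporting;
    matched-control null models for SNPs, indels and structural-variant
    breakpoints and overlap-enrichment statistics; strand-aware positional
    and compartment enrichment profiles around transcription start sites;
    massively parallel reporter assay (MPRA) activity scoring with
    GC-content correction, per-gene normalization and motif-effect
    contrasts; position-weight-matrix scanning with exact p-values; design
    of motif-perturbation reporter libraries; and synthetic-data generators
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
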