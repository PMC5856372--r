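Package: wgbsbias
Title: Bias Diagnostics, Artefact Filtering and Methylation Quantification
    for Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnoses the sequence-composition, coverage and conversion
    biases that bisulfite treatment, PCR amplification and polymerase
    preference imprint on whole-genome bisulfite sequencing (WGBS)
    libraries, and provides the corresponding correction strategies:
    observed-versus-expected mono- and dinucleotide composition reports,
    strand-resolved read counts on GC-skewed references, tandem-repeat
    unit counting in raw reads, GC-content coverage profiles with
    artefact masking, relative coverage trends over feature sets,
    non-conversion read filtering, threshold and unmethylated-control
    background correction, and pooled versus per-cytosine region
    methylation quantification. A generative simulator of bisulfite
    library preparation (degradation at unmethylated cytosines with
    modification protection, context-specific and molecule-correlated
    conversion failure, G-content-dependent PCR) emits aligned reads
    with full ground truth so every diagnostic can be validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
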