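Package: qaseq
Title: Absolute Molecule Quantitation, CNV and Mutation Calling from
    UMI-Barcoded Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("QASeq", "Maintainers", email = "qaseq@example.org",
           role = c("aut", "cre"))
Description: Implements a quantitative amplicon sequencing (QASeq) analysis
    pipeline: absolute quantitation of input DNA molecules by unique
    molecular identifier (UMI) family counting, copy-number calling over
    ensembles of quantitation modules with rank-based (Mann-Whitney U)
    tests, UMI-consensus mutation calling down to 0.1% variant allele
    frequency, inference of tumor fraction and tumor gene ploidy from
    plasma cell-free DNA, and targeted RNA expression profiling
    normalized to reference genes.  A read-level simulator generates
    synthetic FASTQ runs with matched ground truth (Poisson input
    sampling, incomplete barcoding, branching-process PCR amplification,
    multinomial sequencing depth, substitution errors, off-target reads
    and spiked variants) so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
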