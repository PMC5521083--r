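Package: bgnoise
Title: Background Substitution Noise Profiling for Capture-Based Targeted Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes the background substitution noise that limits
    low-allelic-fraction variant detection in capture-based targeted deep
    sequencing. Builds quality-filtered per-site allele counts from aligned
    paired-end reads, classifies non-reference alleles into background error
    versus germline or somatic signal, and estimates per-process error
    contributions: oxidative guanine damage from acoustic shearing, A>K
    substitutions localized at fragment break points, strand-asymmetric damage
    from hybrid selection, and residual sequencing-run errors surviving base
    quality filtration. Includes read-pair overlap consistency analysis,
    break-point nucleotide composition profiling, in-silico down-sampling of
    coverage with false-positive quantification, and a synthetic aligned-read
    simulator that injects each error process with a ground-truth ledger so
    every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    withr,
    yaml,
    Biostrings,
    Rsamtools,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
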