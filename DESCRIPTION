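Package: mdseq
Title: Maximum-Depth Sequencing Simulation and Barcode-Family Consensus Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for maximum-depth sequencing (MDS) of mammalian amplicons:
    exhaustive single-substitution variant libraries with codon-consequence and
    trinucleotide-context annotation, a seeded simulator of barcoded amplicon
    libraries with linear-amplification and sequencing error processes, read
    quality filtering and index/barcode demultiplexing, barcode-family consensus
    mutation calling for ultra-rare variants, detection-limit-corrected mutation
    frequency and fold-change matrices, transcriptional strand-bias and
    expression-quartile analyses, and Poisson-corrected droplet digital PCR
    mutant allele fraction estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
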