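Package: retrocall
Title: Somatic LINE-1 Insertion Calling and Characterisation from Capture Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and mechanistic characterisation of somatic LINE-1 (L1)
    retrotransposon insertions from retrotransposon capture sequencing (RC-seq)
    style data. Provides a synthetic-data simulator (reference genomes with
    decoy L1 copies, mechanistically distinct implanted insertions, capture
    enriched paired-end reads, bisulfite amplicon reads with per-CpG
    methylation), a soft-clip seed-and-extend read aligner with SAM ingestion,
    split-read junction clustering and filtering with TSD/deletion annotation
    and VCF output, tumour-specificity criteria and cohort sensitivity metrics,
    TPRT-hallmark scoring (endonuclease motif, target-site duplication, poly-A
    tail, 3' transduction) with mechanism classification, and L1 promoter CpG
    island methylation quantification from overlapping bisulfite read pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
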