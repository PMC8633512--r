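Package: promcap
Title: Homoeologue-Specific Promoter Capture Analysis for Polyploid Wheat Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing target-capture experiments on
    promoter and 5'UTR sequences of homoeologous genes in allopolyploid wheat.
    Implements high-stringency bait design (repeat soft-masking, 120-nt/60-nt
    candidate tiling, genome-wide specificity screening), capture depth
    profiling with subgenome-specificity verdicts, homozygous-variant haplotype
    grouping across mixed-ploidy panels (shared/unique/reference-identical
    classes, missing-gene and nullisomic-arm calls, cross-ploidy haplotype
    sharing), cliff-edge coverage-gap deletion detection with transposable
    element annotation and MITE hairpin prediction, and IUPAC-consensus
    transcription factor binding site gain/loss scoring across SNP alleles.
    A synthetic-panel simulator generates a toy hexaploid reference with
    homoeologous gene triads and a mixed-ploidy accession panel with planted
    haplotype, introgression and deletion truth, emitting standard FASTA, GFF3,
    VCF and bedGraph files so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
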