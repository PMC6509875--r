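Package: baseTFA
Title: Transcription Factor Activity Inference from Promoter Motif
    Frequencies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the modified BASE (Binding Association with Sorted
    Expression) statistic for inferring which transcription factors drive a
    two-condition gene-expression differentiation profile. Binding strength
    is defined condition-free from motif occurrence counts in promoter
    regions via a Bernoulli-trial probability model, so inference needs only
    a genome, an annotation and a motif library rather than ChIP data.
    Significance is assessed by a permutation null with directional (up /
    down) inference and false discovery rate control. The package also
    provides PWM parsing for TRANSFAC, JASPAR and MEME matrix dialects, a
    MATCH-style information-weighted matrix similarity scanner for promoter
    sequences, a Wilcoxon rank-sum gene-set enrichment companion, and
    synthetic-data generators (toy genomes with planted motifs, null and
    planted-regulator expression ensembles) for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: GeneRegulation, Transcription, MotifAnnotation,
    GeneSetEnrichment, Software
RoxygenNote: 7.3.3
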