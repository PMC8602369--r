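Package: epromoter
Title: Identification of Epromoters and Epromoter-Regulated Gene Clusters
    from Promoter Activity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the enhancer activity of captured gene
    promoters from STARR-seq-style fragment counts, call constitutive,
    induced and repressed Epromoters with an inflection-point threshold on
    the ranked fold-change curve, combine Epromoter calls with
    differential-expression classes, annotate induced genes by the position
    of their nearest composite transcription-factor peak, count ISRE motif
    sites per promoter, identify clusters of co-induced loci by TSS
    distance, assign TAD membership, predict Epromoter-regulated clusters
    from promoter-by-TF binding matrices, and assess positional enrichment
    against a region-shuffling negative-binomial null. A synthetic-genome
    generator with planted ground truth makes the whole chain testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
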