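Package: sedomain
Title: Super-Enhancer Domain Analysis for Tumor/Normal H3K27ac Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of H3K27ac-defined regulatory elements in
    tumor/normal cohorts: promoter/enhancer classification, super-enhancer
    calling by the ROSE tangent cutoff, cross-sample pooling into promoter,
    enhancer and super-enhancer domains with tumor/normal/common specificity,
    shade-controlled Fisher enrichment of transcription-factor binding sites,
    a minimal differential-expression stage for mRNA and enhancer-RNA count
    matrices, distance-resolved analysis of super-enhancer regulatory reach,
    eRNA-mRNA concordance, core-gene-set intersection statistics, preranked
    gene-set enrichment, and a synthetic-cohort generator with planted
    effects for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    jsonlite
Config/testthat/edition: 3
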