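Package: plasmaPGA
Title: Plasma Cell-Free DNA Copy-Number Profiling and Genomic Abnormality Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Shallow whole-genome sequencing analysis of plasma cell-free DNA
    against matched lymphocyte germline DNA: fixed-width (1 Mb) genomic binning,
    GC-corrected log2 copy-number ratio profiles, the Plasma Genomic Abnormality
    (PGA) score and Treatment Efficacy (TEff) index for tumor-burden and
    treatment-response estimation, circular binary segmentation with gain/loss
    calls at recurrent prostate-cancer loci (AR, PTEN, TMPRSS2, 8q), somatic
    mutation calling from cfDNA/germline variant allele fractions, pre/post
    treatment pathway-shift analysis against GMT gene sets, and a seeded
    synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    Biostrings,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
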