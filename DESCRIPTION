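Package: reburden
Title: Mutational Burden Testing of Regulatory Elements in Tumor Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies frequently mutated regulatory elements (FMREs) and
    frequently mutated gene-level regulatory collections (CREAGs) from
    somatic single-nucleotide variants in tumor cohorts. Mutated-sample
    counts per element are tested against a Poisson-binomial background
    model with one empirical per-sample mutation rate each, with
    Benjamini-Hochberg adjustment. Enhancers are mapped to target genes by
    one-sided Spearman correlation of H3K27ac activity with gene expression
    within shared topologically associating domains (TADs). Downstream
    modules quantify expression fold changes by mutation status,
    transcription-factor binding-site mutation enrichment, and
    super-enhancer gene enrichment along the burden ranking. A seeded
    synthetic-cohort generator provides fully reproducible toy data with
    the same statistical structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
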