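Package: neoforge
Title: Neoepitope Discovery and Prioritization from Somatic Variants and
    Expressed Gene Fusions
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested engine for MHC class I neoantigen discovery in
    structurally complex tumors. From filtered somatic variants (VCF with
    effect annotation), expressed fusion calls (Arriba-style tables),
    per-base coverage tracks and transcript abundance estimates, it
    reconstructs mutant protein contexts, enumerates candidate 8-11-mer
    peptides from missense variants, in-frame and frameshift indels and
    fusion junctions, scores them with a pluggable percentile-rank binding
    predictor, and ranks candidates with a bounded multi-component priority
    score (logistic rank weight, tanh expression, VAF clonality,
    agretopicity-based foreignness, exact self-similarity veto). It also
    computes callable-territory-normalized tumor mutational burden, Ti/Tv
    ratios, breadth of coverage, fusion abundance (FFPM), and DNA-RNA
    concordance classification of candidate amplifications versus capture
    artifacts. A seeded synthetic-cohort generator makes the full pipeline
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
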