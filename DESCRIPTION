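Package: regvar
Title: Regulatory Variation Analysis of GWAS Index Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to move from GWAS index variants to mechanistic regulatory
    hypotheses when full summary statistics are unavailable. The package
    fine-maps association loci to probable causal variants with PICS-style
    causal probabilities, colocalizes them with cis-eQTL causal sets by
    product of probabilities (CLPP), detects allele-specific alteration of
    transcription factor binding sites by scanning position weight matrices
    against order-k Markov backgrounds with exact score p-value distributions,
    validates candidate motifs against permuted-matrix and matched-variant
    negative controls with one-sided rank tests, gates hits by chromatin
    state and transcription factor expression, and assembles
    variant-TF-eGene evidence triples. A synthetic-data generator with a
    planted ground-truth manifest makes every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
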