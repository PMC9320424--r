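# regvar

Regulatory-variation analysis of GWAS index variants: from association
loci to mechanistic *variant → transcription factor → gene* hypotheses,
designed for the common situation where only index variants — not full
summary statistics — are available.

## What it does

Most GWAS hits for complex traits land in non-coding DNA. `regvar`
implements a two-branch analysis to explain them:

* **Fine-mapping & colocalization.** Loci are LD-expanded around each
  genome-wide-significant index variant (p ≤ 5·10⁻⁸) and fine-mapped with
  PICS-style causal probabilities: member *i* at LD *r²* with an index of
  strength *S* = −log₁₀ *p* is scored by the Gaussian density with mean
  *r²·S* and spread *k·√S·(1 − r^c)^½*, normalized per locus. Causal sets
  (probability > 10%) from GWAS and cis-eQTL fine-mapping are intersected,
  and each (variant, eGene, tissue) pair is scored by the colocalization
  posterior probability CLPP = P₍GWAS₎ · P₍eQTL₎ under independence, with
  a one-sided hypergeometric test for eQTL enrichment.
* **Allele-specific TF-binding alteration.** Variants inside ChIP-seq
  peaks are scanned against PWM libraries (JASPAR/TRANSFAC dialects) with
  weights *w* = log₂ P(site | PWM) − log₂ P(site | order-2 Markov
  background), exact score p-values by dynamic programming, and the
  retention filters weight > 1, weight difference > 1, p < 10⁻³,
  p-value ratio > 10. Candidate motifs are validated against permuted
  matrices and matched random variants (1:10 strict, 1:1000 relaxed
  attribute matching), then gated by active chromatin states (18-state
  vocabulary) in brain biosamples and TF expression ≥ 2 TPM.

Where both branches and a tissue-matched TF→target record agree, the
package emits evidence triples (variant, TF, eGene). A synthetic-data
generator with a planted ground-truth manifest makes the entire pipeline
verifiable end to end without any downloads.

## Worked example

Simulate a full study (2 Mb genome, 20 loci, 12 motifs, planted causal,
colocalizing and binding-alteration variants) and run the pipeline:

```r
library(regvar)

sim <- simulateRegulatoryData(simulationConfig(seed = 7))
res <- runPipeline(sim, pipelineParams(seed = 7))

res$coloc_headline[1:3, ]
#>   variant_id egene       tissue gwas_pics eqtl_pics clpp
#> 1   rsI00001  G001 Brain_Cortex       0.6       0.6 0.36
#> 2   rsI00002  G052 Brain_Cortex       0.6       0.6 0.36
#> 3   rsI00003  G023 Brain_Cortex       0.6       0.6 0.36

res$evidence[, c("variant_id", "tf_name", "egene", "eqtl_tissue")]
#>   variant_id tf_name egene       eqtl_tissue
#> 1    rsB0025    TF01  G016 Brain_Hippocampus
#> 2    rsB0026    TF02  G009 Brain_Hippocampus
#> 3    rsB0027    TF03  G015      Brain_Cortex
#> 4    rsB0028    TF04  G047 Brain_Hippocampus

unlist(res$report[c("n_significant", "n_causal", "n_coloc_pairs",
                    "n_scan_pass_variants", "n_confirmed_variants",
                    "n_evidence_triples")])
#>        n_significant             n_causal        n_coloc_pairs
#>                   20                   10                    6
#> n_scan_pass_variants n_confirmed_variants   n_evidence_triples
#>                   47                   23                    4
```

Reading the output: of 23 association records, 20 index variants reach
genome-wide significance; fine-mapping leaves 10 causal variants
(probability > 0.10), 6 of which colocalize with an eQTL at CLPP > 0.10
(here 0.36 = 0.6 × 0.6, matching the planted probabilities). On the
binding branch, 47 scanned variants pass the four retention filters for
at least one motif, 23 survive the negative-control confirmation, and the
chromatin, expression and tissue-matching gates leave 4 evidence triples
— exactly the 4 that were planted, with no false triple.

Individual stages are exported and composable: `filterGenomewideSignificant()`,
`ldExpand()`, `picsProbabilities()`, `overlapPics()`, `clpp()`,
`enrichmentFisher()`, `estimateMarkov()`, `buildVariantWindows()`,
`scanVariants()`, `applyScanFilters()`, `permuteMatrix()`,
`sampleMatchedControls()`, `confirmMotifPairs()`, `activeRegionFilter()`,
`tfExpressionFilter()`, `mechanisticEvidence()`. File readers cover
JASPAR/TRANSFAC matrices, BED (peaks, ChromHMM segmentations), GCT/TSV
expression, FASTA genomes and PICS snapshot tables with configurable
column maps; `writeSimulation()`/`readSimulation()` round-trip a complete
simulated study through standard formats.

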