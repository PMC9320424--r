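---
title: "From GWAS index variants to regulatory mechanism: the methods behind regvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS index variants to regulatory mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regvar)
```

# The problem

Most disease-associated variants found by GWAS fall in non-coding DNA, and
for many studies only the index variants — not full summary statistics —
are public. `regvar` implements an analysis strategy for exactly this
situation. It asks, for each association locus: which variant in the locus
is plausibly causal, does that variant also drive expression of a nearby
gene (a cis-eQTL), and does its alternate allele measurably change a
transcription factor's binding site? When all three lines of evidence meet
in the same tissue, the package assembles a mechanistic hypothesis of the
form *variant → TF → regulated gene*.

The pipeline has two complementary branches that are joined at the end:

1. **Colocalization branch** — fine-mapped GWAS causal probabilities are
   intersected with fine-mapped cis-eQTL probabilities; the product of the
   two (CLPP) scores each (variant, eGene, tissue) pair.
2. **Binding branch** — variants inside ChIP-seq peaks are scanned against
   PWM libraries with allele-specific scoring against Markov backgrounds,
   validated against two negative-control systems, and gated by chromatin
   state and TF expression.

# Fine-mapping (PICS-style causal probabilities)

Given an index variant with association strength $S = -\log_{10} p$, each
locus member at LD $r^2$ with the index is assigned the Gaussian density
of the observed index association under the hypothesis that this member is
causal:

$$\mu_i = r^2_i\,S,\qquad
  \sigma_i = k\,\sqrt{S}\,\bigl(1 - r_i^{c}\bigr)^{1/2},\quad r_i=\sqrt{r^2_i},$$

with defaults $k = 0.5$ and $c = 3.2$; probabilities are normalized to sum
to 1 within each locus. The functional form guarantees three properties the
tests assert for any $k, c > 0$: normalization, index dominance (the index
attains the maximum), and monotonicity in $r^2$. A $\sigma$ floor of
$10^{-6}$ handles perfect LD; members at $r^2 = 1$ share probability
equally. In replication work the snapshot route
(`readPicsTable()` + `pics_source = "table"`) is preferred, because
published PICS tables were produced with the original tooling; the internal
implementation exists so the pipeline is self-contained on simulated data.
Causal sets use a strict cutoff, probability $> 0.10$.

# Colocalization

Under independence of the two fine-mapping experiments the colocalization
posterior probability of a variant $v$ for eGene $g$ in tissue $t$ is the
product $\mathrm{CLPP} = P_\text{GWAS}(v)\,P_\text{eQTL}(v,g,t)$, reported
when $> 0.10$ (strict). Headline counts deduplicate to the best tissue per
(variant, eGene). Enrichment of causal variants in eQTL regions uses the
one-sided hypergeometric tail (`stats::phyper`), with the universe defined
as all LD-expanded variants — the only construction expressible from the
inputs the pipeline consumes; this choice is configurable upstream of the
2x2 counts.

# Allele-specific binding-site scanning

## Background models

Order-2 Markov models capture dinucleotide structure, in particular CpG
depletion, without overfitting. Estimation counts (context, next-base)
transitions over the training sequences *and their reverse complements*,
wrapping around at the end of each contiguous A/C/G/T run (circular
counting). Two consequences matter:

* the stationary distribution (proportional to the pseudocount-augmented
  context totals) makes every estimated model assign *exactly* equal
  probability to a sequence and its reverse complement — the test suite
  checks this to numerical precision, and double-stranded scanning
  inherits the symmetry;
* with a pseudocount (default 1 per cell) no transition has probability
  zero, so log-scores stay finite.

One background is estimated per consequence set (intergenic/UTR, intronic,
regulatory, non-coding) from the peak sequences overlapping that set's
variants, with a pooled "global" model as fallback when a set has fewer
than 10 kb of training sequence — a per-set corpus below that is dominated
by sampling noise at order 2 (16 contexts x 4 bases).

## Weights and score p-values

A candidate site of length $L$ at some offset scores
$w = \log_2 P(\text{site}\mid\text{PWM}) -
     \log_2 P(\text{site}\mid\text{background})$,
the background conditioned on the bases immediately 5' of the site within
its window; log base 2 throughout. PWM frequencies use
$(n + pc/4)/(N + pc)$ per column. The p-value of a weight is
$P(W \ge w)$ under the background, computed exactly by dynamic programming
over motif positions and background contexts on a discretized score grid
(default 0.01 log2 units). Score increments are rounded on a half-bin
internal grid, bounding the accumulated error by $L \cdot \text{bin}/4$;
the acceptance tests verify agreement with exhaustive $4^L$ enumeration to
within two grid bins for $L \le 6$. The initial context is marginalized
with the stationary distribution. P-values are clamped to
$[10^{-16}, 1]$; the floor only matters for sites that outscore every
achievable background word.

## Variant scanning and retention

Only sites that cover the variant base are scored (an allele contrast is
undefined for sites the variant cannot touch), on both strands, for both
alleles; the maximum-weight hit per allele is kept, with deterministic tie
breaking (+ strand, then lowest offset). The four retention filters are
all strict: best weight $> 1$, weight difference $> 1$, best site p-value
$< 10^{-3}$, p-value ratio $> 10$. The ratio is direction-free
(larger/smaller p-value); the direction lives in the `effect` call
(*disrupt* when the reference allele binds better, *create* otherwise).

At these thresholds a chance (non-planted) in-peak variant passes for
roughly 1–2% of (variant, motif) pairs in simulation: a random site that
clears $p < 10^{-3}$ usually covers an informative column, so the
difference and ratio filters follow almost automatically. This false-pass
rate is intrinsic to the thresholds; it is the statistical confirmation
stage, not the filters, that controls false motifs.

# Negative controls and confirmation

Two negative-control systems validate candidate motifs: (1) five
permuted replicates of every matrix — column order
shuffled and values shuffled within each column, which preserves the
per-column value multisets and hence the information content exactly; and
(2) matched random variants sampled 1:10 under strict attribute windows
(TSS distance ±5000 bp, gene density ±5 per 100 kbp, LD partners ±50 at
$r^2 \ge 0.1$, same chromosome, coding class and variant type) and 1:1000
under relaxed matching (class and type only, any chromosome). Controls are
scanned by the identical pipeline, including the retention filters, so the
observed and control ratio distributions answer the same question and are
exchangeable when nothing is planted.

Confirmation offers two decision rules (`confirmMotifPairs(method=)`):

* **Per-pair quantile (default).** A pair is confirmed when its p-value
  ratio exceeds the $1-\alpha$ empirical quantile of the motif's control
  ratios in the permuted and 1:10 systems, and again in the 1:1000
  system. This matches reporting per-variant significance counts, and it
  is the rule the pipeline uses: when only a minority of a motif's
  observed pairs carry a real effect, a motif-level rank test compares
  medians of two truncated distributions and loses the signal entirely,
  while the planted pairs' ratios sit orders of magnitude above the
  control quantiles.
* **Motif-level Wilcoxon.** One-sided rank-sum (exact by enumeration for
  small tie-free samples, normal approximation with tie and continuity
  correction otherwise) of observed versus control ratios per motif,
  required in the permuted and 1:10 systems and re-required at 1:1000.
  The per-motif p-values (with Benjamini–Hochberg adjustments) are
  computed and reported under both rules.

A Shapiro–Wilk check on the ratio distribution is reported to document why
a nonparametric route is used. Motifs without control observations are
flagged unconfirmable and never confirmed.

# Chromatin context and evidence assembly

Confirmed variants must overlap an active chromatin state (TssA, TssFlnk,
TssFlnkU, TssFlnkD, Tx, TxWk, EnhG1, EnhG2, EnhA1, EnhA2, EnhWk,
ZNF/Rpts under the 18-state vocabulary) in at least one selected brain
biosample — any-one-of suffices. Coordinates follow each format's native
convention: segments are 0-based half-open, variants 1-based, and a
variant whose 1-based position equals a segment's exclusive end *is* the
segment's last base (conversions are centralized in `bedToOneBased()` /
`oneBasedToBed()`). Confirmed TFs must reach 2 TPM (inclusive) in at
least one selected brain tissue; TFs missing from the expression matrix
are retained with a warning by default, because an absent row more often
means an identifier mismatch than absent expression.

An evidence triple (variant, TF, eGene) is emitted when the confirmed pair
coincides with a causal eQTL record for the same variant and a TF→target
record for the same TF and gene, with the eQTL tissue and TF-target tissue
equivalent under a user-editable mapping table (`defaultTissueMap()`)
linking the three tissue vocabularies involved.

# The synthetic-data generator

`simulateRegulatoryData()` produces every input the pipeline consumes plus
a ground-truth manifest. Its defaults are the package's study conditions:
a 2 Mb, two-chromosome genome at GC 0.42 with CpG observed/expected 0.25
(thinning rate derived in closed form so the realized ratio matches); 60
genes; 20 loci of 15 variants; 12 motifs of 8–14 bp targeting 10–16 bits,
whose sharp columns carry zero or near-zero minor counts as curated
matrices do; 10 planted causal loci (PICS 0.6 at the index, the remainder
spread below 0.10; non-causal loci uniform at 1/15), 60% of them planted
as colocalizing eQTLs (eQTL PICS 0.6, so CLPP $= 0.36 > 0.10$ by
construction); two planted binding-alteration variants per motif plus one
extra on each of the first four motifs, which anchor four evidence
triples with tissue-matched eQTL, TF-target and expression support; 40
decoy peaks with three decoy variants each; 300 bp peaks each containing
one embedded motif instance; a 2000-variant matched-control pool that
avoids peak footprints (a pool variant on a planted instance — essentially
impossible at real genome scale but ~1% likely here — would inject a
planted-sized ratio into a motif's control null); and ChromHMM-style
tracks for three brain biosamples at 50% active fraction, with the
planted variants' segments forced active in the first biosample.

What the simulation does **not** emulate: realistic LD from population
genetics (r² values are drawn from a decaying profile, not a coalescent),
ChIP-seq read-level noise and peak-calling artifacts, motif co-occurrence
and TF cooperativity, and the composition biases of real bound regions
(real peaks are enriched for true binding sites beyond the one planted
instance). Passing recovery tests therefore demonstrates that the
machinery is correct and calibrated on data satisfying its assumptions,
not that the thresholds are optimal for any particular real dataset.

# Numerical and design choices

* **Problem sizes.** The test suite exercises the default conditions over
  five replicate seeds for recovery and twenty reduced null
  configurations (one 0.4 Mb chromosome, 6 motifs, no planted effects)
  for the type-I check; exhaustive oracles run at $L \le 6$, order
  $\le 1$, where $4^L \cdot 4^k$ enumeration is exact and fast.
* **Determinism.** Every random step derives from a single seed; two runs
  of the generator are byte-identical on disk, and matched sampling and
  matrix permutation take explicit seeds.
* **Degenerate inputs.** Empty variant tables flow through to an all-zero
  funnel; single-member loci get probability 1; constant samples return a
  not-applicable sentinel from the normality check; motifs longer than
  the scan window are skipped with a warning; a declared reference allele
  that contradicts the genome is an error naming the variant.
* **No staged resume.** The pipeline is one deterministic in-memory
  function; persisting intermediates is left to the caller
  (`writeSimulation()` covers the generator side), which keeps
  stage-equivalence trivially true rather than a property to test.
* **Indels** are out of scope end to end; the scanner requires
  single-base alleles because length-changing alleles break window
  alignment.

# Known limitations

* The PICS constants $(k, c)$ are calibration choices; published PICS
  snapshot tables remain the faithful route for replication, and the
  internal implementation is validated on structural properties, not
  against the original software's output.
* The per-pair quantile rule's level is approximate at small control
  sample sizes (an empirical 95th percentile of ~15 values is noisy); the
  two-stage requirement across independent control systems damps, but
  does not remove, this noise.
* The Fisher-enrichment 2x2 construction is one of several defensible
  choices; published enrichment p-values from the original snapshot data
  are not expected to be reproduced from other inputs.
* Weight p-values are right tails on a discretized grid; ratios of two
  clamped p-values saturate once either allele hits the $10^{-16}$
  floor.
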