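---
title: "Methods: annotation, LD extension, enrichment and regulatory circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation, LD extension, enrichment and regulatory circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcircuits)
```

## The analysis model

`snpcircuits` treats a disease-variant catalog as a set of point positions
on a genome and asks, stage by stage: does each variant carry regulatory
evidence; does evidence transfer from its LD neighbourhood; are the
evidence categories enriched relative to a background variant set; which
tissue-specific TF–element–target interactions does the variant set
perturb; and how tissue-specific are the genes in those circuits?

The stages are deliberately modular, joined by plain files, so each is
independently testable. Every assumption that matters is a named parameter
with the field's conventional default.

### Coordinates

All intervals are 0-based half-open internally (the BED convention); SNP
and eQTL positions are 1-based and converted on read. A 1-based position
$p$ overlaps $[s, e)$ iff $s \le p - 1 < e$. Chromosome names are matched
as exact strings; `normalize_chrom()` converts between "chr1" and "1"
styles explicitly, because silent prefix coercion is a classic source of
empty joins. Nearest-feature distance is 0 inside the feature and
otherwise counts bases such that an immediately adjacent position is 1 bp
away; ties are broken by distance, then lexicographic feature id, making
results order-independent. Distance is measured to the gene body (not the
TSS): the nearest-gene baseline is used only as a gene *set*, and the
body convention is the more common default in genome-arithmetic tools.

### Annotation

Three regulatory categories are assigned per SNP:

* **motif** — overlap with at least one TF motif occurrence interval
  (occurrences are taken as provided; no PWM scanning);
* **promoter/enhancer** — overlap with at least one promoter or enhancer
  interval; the two element types are merged for coverage summaries but
  kept distinct for circuits, which treat them differently;
* **eQTL** — at least one cis-association at FDR ≤ 0.05 (threshold
  inclusive, applied at analysis time rather than at file read, so one
  table serves any threshold).

Coding variants are additionally flagged when within 2 residues of a
ligand-binding site or 7 residues of a phosphorylation site on the same
protein. The genic classifier is intentionally minimal
(exonic/intronic/intergenic): only the exonic-versus-noncoding split feeds
any downstream decision, and reproducing a transcript-aware annotator
would add surface without changing results.

Regulatory flags are computed for *all* SNPs, coding or not; coverage
summaries are reported under both an all-SNPs denominator and a
noncoding-only denominator (`summarize_annotations()`), because the
appropriate denominator is a presentation choice, not an analysis one.

### LD extension

`find_proxies()` keeps pairs with r² ≥ 0.8 (inclusive) at distance ≤
500,000 bp (inclusive), one hop only — evidence transfers from direct
proxies of a reported SNP, never proxy-of-proxy, which would dilute the
guarantee that every extended flag is witnessed by a genuine LD partner.
The r² table is the only LD source; computing r² from genotypes is out of
scope. Distances come from the table when present and fall back to
coordinates; pairs with no usable distance fail the window filter rather
than passing silently. Extension is a per-flag logical OR, hence monotone
(base-true stays true) and idempotent; both properties are asserted in the
test suite.

### Enrichment

`fisher_exact_2x2()` computes the two-sided exact P by summing
hypergeometric probabilities of tables at the observed margins whose
probability is ≤ that of the observed table, with a relative tolerance of
1e-7 in the comparison (the convention R's `fisher.test` also uses; the
suite cross-checks against both `stats::fisher.test` and an exhaustive
enumeration from binomial coefficients for every table with total ≤ 60).
Degenerate tables are handled at the caller: a category absent from both
arms reports P = 1 with an `NA` fold; a zero background count leaves the
fold `NA` rather than infinite. Because genome-scale eQTL enrichments
routinely underflow double precision, the report carries a `log10_p`
column accumulated in log space instead of clamping at some printable
bound.

The background is used as-is — catalog SNPs are not removed from it. With
backgrounds of ~10× the catalog size the effect on the fold is second
order, and any exclusion rule would itself be a modelling choice.

Power stratification bins records into equal-occupancy (quantile) strata
of −log₁₀ P (default 10 bins) and correlates the per-bin annotated
fraction with the bin midpoint, taken as (min + max)/2 of the bin's
−log₁₀ P values. Quantile binning keeps every stratum estimable; a
stratum below 5 records is an error advising fewer bins. With exactly two
strata the correlation is ±1 by construction and its P value is reported
as `NA`.

### Circuits

A SNP perturbs a promoter if it falls in the promoter body or the
strand-aware flank from 400 bp upstream of the 5' end to 50 bp downstream
of the 3' end; both flank windows include their outer boundary base
("400-bp upstream to 50-bp downstream" reads as inclusive spans).
Enhancers have no flank. Unstranded promoters are oriented as + strand —
real promoter resources are stranded, but synthetic or reduced inputs may
not be. Every network edge through a hit element, in the requested tissue,
becomes a perturbed interaction carrying all witnessing SNP ids; the edge
set is always a subset of the input network, deterministic and invariant
to input order. Circuits are built per (trait, tissue) pair, with SNPs
admitted at association P < 0.05 by default (the catalog's significance
convention; configurable via `circuit_p`).

The candidate-novel screen uses Benjamini–Hochberg q-values with a strict
q < 0.1 cut.

### Tissue specificity

The z-score
$z_E(i,t) = (E(i,t) - \langle E(i)\rangle)/\delta_E(i)$ uses per-tissue
*mean* expressions as its inputs, and computes $\langle E(i)\rangle$ and
$\delta_E(i)$ across those per-tissue means with the sample (n−1) SD.
Pooled-sample statistics would weight tissues by sample count, which the
per-tissue indexing of $E(i,t)$ does not support. When $\delta_E(i) = 0$
all z are defined as 0. The direction is: larger z = higher expression in
that tissue. No log-transform is applied by default; a
`log_transform = TRUE` switch applies log2(x+1) first for users who prefer
variance-stabilised means. Tissue-expressed calls use RPKM ≥ 1 in
strictly more than 80% of samples — a gene at exactly 80% does not
qualify.

## The synthetic-data generator

`sim_config()` / `simulate_inputs()` generate every input with planted
ground truth. What it emulates is the *statistical structure* the analysis
assumes, not human genomics:

* a packed genome of non-overlapping gene/promoter/enhancer/motif units,
  with promoters stranded and adjacent to gene 5' ends and half the motifs
  nested inside enhancers so multi-category placement is possible;
* catalog SNPs placed into disjoint placement pools (motif-only,
  element-only, both, neither) according to planted per-category
  probabilities; background SNVs likewise at lower probabilities, so the
  planted enrichment fold per category is exactly
  `prob_catalog / prob_background`. The defaults plant catalog proportions
  of 12.6% / 34.8% / 38.8% (motif / promoter-enhancer / eQTL) with folds
  1.32 / 1.42 / 14.6 — the study conditions this package is designed
  around;
* LD taggings for a configured fraction of *unannotated* catalog SNPs:
  each receives a proxy at r² ≥ 0.8 within 500 kb placed inside a
  functional pool, plus distractor pairs that fail the r² or the distance
  filter;
* per-tissue networks over a reserved set of elements that is excluded
  from the general placement pools — so the planted perturbed edges are
  exactly the recoverable ones, and precision = recall = 1 is the correct
  expectation, not an approximation. Promoter witness SNPs cycle through
  the element body and the two outermost flank bases to keep the boundary
  arithmetic honest on both strands;
* log-normal expression (log-mean 1, log-SD 1, tissue effect SD 0.3,
  sample noise SD 0.5 on the log scale) with planted tissue-specific genes
  whose tissue effect sits 4 SDs above the rest — strong enough that
  max-z recovery is expected every time, which is what the recovery test
  asserts;
* disease genes drawn with an 8-fold excess weight on perturbed-circuit
  genes (excess 0 gives the null draw).

Each stage draws from its own RNG stream derived from the master seed, so
changing one stage's parameters cannot perturb another stage's data. With
a fixed seed every emitted file is byte-identical across runs.

What the generator does **not** emulate — and therefore what passing tests
do *not* establish about real data: realistic LD block structure and
allele frequencies (taggings are planted pairs, not coalescent
haplotypes); overlapping or nested genes; correlated category membership
(motif, element and eQTL status are drawn independently); eQTL effect
sizes; catalog ascertainment bias; and any genome-build issues. Results on
real inputs depend on the quality of the supplied tracks, eQTL maps and
networks in ways synthetic recovery cannot certify.

## Problem sizes and runtime choices

The default simulation is sized for interactive use: one 10-Mb chromosome,
200 genes, 150 enhancers, 300 motif occurrences, 5,000 catalog SNPs,
50,000 background SNVs, 4 tissues × 50 samples — a full
simulate-plus-pipeline run completes in well under a minute. The test
suite verifies exact-test oracle equivalence exhaustively for all 2×2
tables with total ≤ 60, interval-query oracle equivalence on 20 seeded
instances of 10⁴ intervals × 1,000 queries, fold recovery at 5,000/50,000
per arm over 20 seeds per planted fold, and circuit/z-score/LD recovery on
reduced genomes (4-Mb chromosome, 60–120 genes) chosen so that 20-seed
replications stay fast while every code path — including both promoter
strands and both flank boundaries — is exercised.

## Known limitations

* The interval index answers point queries only; range-overlap,
  merge/subtract and k-nearest are out of scope.
* The genic classifier has no UTR/splice subcategories, and protein-site
  mapping requires a user-supplied coding-variant table; no consequence
  prediction is attempted.
* Enrichment is marginal per category: no LD-aware or covariate-matched
  background construction.
* TF→element→target links are taken as input; the package neither infers
  networks nor predicts allele-specific binding changes.
* One-hop LD extension deliberately under-reaches long LD chains.
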