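# snpcircuits

Integrative functional annotation and tissue-specific regulatory-circuit
analysis for disease-associated variants.

Most variants that phenome-wide (PheWAS) and genome-wide (GWAS) association
studies link to disease lie outside protein-coding sequence, so their
mechanism cannot be read off a gene model. `snpcircuits` implements the
standard integrative strategy for interpreting such variants:

1. **Functional annotation** — each catalog SNP is tested for overlap with
   transcription-factor (TF) motif occurrences, promoter/enhancer elements,
   and significant cis-eQTLs (FDR ≤ 0.05 in at least one tissue); exonic
   variants are additionally flagged when they fall at protein–ligand
   binding sites (±2 residues) or phosphorylation sites (±7 residues).
2. **LD extension** — evidence is propagated from proxy SNPs in strong
   linkage disequilibrium (r² ≥ 0.8 within a 500-kb flank on each side): a
   reported SNP counts as annotated if it, or any direct proxy, carries the
   annotation.
3. **Enrichment vs background** — for each category the 2×2 table of
   annotated/unannotated counts in the catalog vs a background variant set
   is tested with a two-sided Fisher's exact test; the headline statistic is
   the fold-change `(a/(a+b)) / (c/(c+d))`. Coverage is also stratified by
   association strength (−log₁₀ P quantile bins, Pearson correlation).
4. **Perturbed regulatory circuits** — SNPs are mapped onto promoters
   (element body plus a strand-aware 400-bp-upstream / 50-bp-downstream
   flank) and enhancers (body only); every TF → element → target edge of a
   tissue-specific regulatory network passing through a hit element becomes
   a promoter- or enhancer-perturbed interaction. Circuit gene modules are
   compared to a nearest-gene baseline by disease-gene enrichment.
5. **Tissue specificity** — genes are called tissue-expressed at
   RPKM ≥ 1 in > 80% of a tissue's samples, and scored with the
   specificity z-score

   z_E(i,t) = (E(i,t) − ⟨E(i)⟩) / δ_E(i),

   where E(i,t) is gene *i*'s mean expression in tissue *t* and ⟨E(i)⟩,
   δ_E(i) are the mean and (n−1) SD of those per-tissue means. Larger z
   means higher expression in that tissue.

A first-class synthetic-data generator (`sim_config()`,
`simulate_inputs()`) emulates every input — association catalogs, BED
tracks, eQTL and LD tables, tissue networks, expression matrices,
disease-gene tables — with planted ground truth (enrichment folds, LD
taggings, perturbed edges, tissue-specific genes), so the whole pipeline is
testable without any external download.

## Worked example

Simulate a full input set (1 × 10-Mb chromosome, 200 genes, 5,000 catalog
SNPs, 50,000 background SNVs, 4 tissues × 50 samples) and run the whole
pipeline:

```r
library(snpcircuits)

cfg <- sim_config(seed = 42)
simulate_inputs(cfg, "sim")
pc  <- pipeline_config("sim",
         circuits = tibble::tibble(trait = "trait_1", tissue = "tissue_1"))
res <- run_pipeline(pc, "out")

res$enrichment
#> # A tibble: 6 × 8
#>   category              a     b     c     d fold_change  p_value  log10_p
#>   <chr>             <int> <int> <int> <int>       <dbl>    <dbl>    <dbl>
#> 1 motif               598  4402  4745 45255        1.26 4.61e- 8    -7.34
#> 2 promoter_enhancer  1758  3242 12278 37722        1.43 7.06e-57   -56.2
#> 3 eqtl               1954  3046  1354 48646       14.4  0        -1278.
#> 4 at_least_1         3265  1735 16809 33191        1.94 0         -410.
#> 5 more_than_1         963  4037  1536 48464        6.27 0         -373.
#> 6 all_3                82  4918    32 49968       25.6  2.31e-59   -58.6
```

`a`–`d` are the Fisher 2×2 cells (catalog annotated / not, background
annotated / not). The planted folds at these defaults are 1.32 (motif),
1.42 (promoter/enhancer) and 14.6 (eQTL); the estimates above recover them
to sampling error, and `log10_p` keeps the eQTL P value informative where
the linear scale underflows. The simulated catalog has 65.3% of SNPs with
at least one regulatory category, rising to 83.2% after LD extension
(`res$summaries`).

The perturbed circuit for `trait_1` in `tissue_1` recovers exactly the
planted edges, and its gene module is far more disease-enriched than the
nearest-gene baseline:

```r
glance(res$circuits[[1]])
#>   trait   tissue   n_edges n_promoter_perturbed n_enhancer_perturbed n_genes
#> 1 trait_1 tissue_1       6                    2                    4       9

res$comparison[, c("module", "a", "b", "fold_change", "p_value")]
#>   module           a     b fold_change   p_value
#> 1 circuit          7     2        6.46 0.0000257
#> 2 nearest_gene    19   107        1.01 1
```

Result objects have `tidy()`/`glance()` methods and `autoplot()` figures
(enrichment folds, stratification trend, circuit composition, z-score
profiles). All stage outputs are written as deterministic TSV/JSON under
the output directory.

## Package layout

- `R/intervals.R` — GenomicRanges-backed interval index (point overlap,
  nearest feature with deterministic tie-breaks).
- `R/io.R` — strict readers/writers for all TSV/BED schemas.
- `R/annotate.R`, `R/ld.R` — functional annotation and LD extension.
- `R/enrichment.R` — exact test, category enrichment, power stratification.
- `R/circuits.R` — element mapping, perturbed circuits, nearest-gene
  baseline, disease-gene enrichment, FDR screen.
- `R/expression.R` — tissue-expressed calls and specificity z-scores.
- `R/simulate.R` — the synthetic-data generator with planted truth.
- `R/pipeline.R` — configuration and the one-shot `run_pipeline()`.

See `vignettes/snpcircuits-methods.Rmd` for the modelling choices,
parameter semantics and limitations.
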