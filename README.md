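# dclineage

Cross-platform transcriptomic lineage classification of dendritic-cell
subsets.

## The problem

A rare BDCA2⁺CD123⁺CD56⁺ dendritic-cell (DC) population in human blood
carries the surface phenotype of plasmacytoid DCs (pDCs) and has been
proposed as the normal counterpart of blastic plasmacytoid dendritic cell
neoplasm (BPDCN). Whether it truly belongs to the pDC lineage or to the
myeloid DC (mDC) lineage is a transcriptome-wide question — complicated by
the fact that the query population is measured by RNA-seq while reference
panels of sorted immune lineages (pDC, BDCA1/BDCA3 mDC, monocytes,
neutrophils, NK, B, T) exist on microarrays. `dclineage` implements the
full analysis chain for this comparison, plus a synthetic two-platform
data generator with planted ground truth so every stage can be validated
end to end.

## The methods at its core

* **Probe-restricted RPKM.** A read counts for a gene only if it is
  uniquely mapped and overlaps, by ≥ 1 nucleotide, the gene regions
  targeted by the array's probes (half-open coordinates), so both
  platforms measure the same bases. For gene *g* with counting-region
  length *L_g* (bp) and *N* uniquely mapped reads in the sample,

  RPKM_g = count_g / (L_g / 1000) / (N / 10⁶).

* **Rank-invariant normalization.** Iteratively keep genes with
  |rank_target − rank_reference| / n < 0.05 (ranks recomputed in the
  surviving set), then map the sample onto the reference through a
  monotone running-median curve through the invariant pairs, linearly
  interpolated and end-slope extrapolated.

* **Differential sets.** Unreplicated query contrast: |Δ log₂ mean| ≥
  log₂ 2. Replicated array contrast (BPDCN vs pDC): empirical-Bayes
  moderated t with s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), prior (d₀, s₀²)
  from method-of-moments on log s²_g, p-values on d₀ + d_g df,
  Benjamini–Hochberg adjusted at 0.05, after deleting genes with RPKM
  < 10 across the query samples.

* **Directional concordance.** For a query-derived gene set, the fraction
  of matched reference genes whose pooled-mDC-minus-pDC mean difference
  has the query's sign.

* **Lineage assignment.** Complete-linkage clustering on 1 − Pearson
  distances of the merged, gene-wise z-scored matrix, plus PCA; a query
  takes the majority branch of the subtree it first merges with.

## Worked example

```r
library(dclineage)
report <- run_pipeline(pipeline_config(sim = sim_config(seed = 42)))
print(report)
```

```
<analysis_report> seed 42
  query DE sets: 498 up / 581 down (fold-change >= 2)
  concordance with mDC-vs-pDC: up 442/498 (89%), down 493/581 (85%)
  lineage of CD56pos_1: myeloid
  lineage of CD56neg_1: pDC
  BPDCN-high vs CD56+ contrast: 586/638 (92%); BPDCN-low: 543/606 (90%)
```

Reading the output: of the 498 genes ≥ 2-fold higher in the CD56⁺ query
than in the CD56⁻ query, 89% are also higher in mDCs than pDCs in the
reference arrays (and 85% of the down-set are lower) — the signature of a
myeloid population. Consistently, the clustering stage places the CD56⁺
query on the myeloid branch and the CD56⁻ query with the pDCs, and the
BPDCN arm finds the BPDCN-high/-low moderated-t sets concordant with the
CD56⁺-vs-CD56⁻ contrast. The planted truth is recovered exactly:

```r
up <- report$concordance_planted$up
sprintf("planted up-set recovery: %d/%d = %.1f%%",
        up$n_concordant, up$n_matched, up$percent_concordant)
#> "planted up-set recovery: 300/400 = 75.0%"
```

(the generator plants 75% directional concordance in the 400-gene sets).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/xlineage.R run --seed 3 --outdir out/
Rscript inst/cli/xlineage.R simulate --seed 3 --outdir data/
```

which writes BED reads/annotations, TSV matrices, the newick dendrogram,
PCA scores and a JSON report.

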