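# ProteoSect

Sectionalized imputation and two-group comparative analysis of label-free
quantification (LFQ) proteomes.

## The problem

LFQ proteomics of two patient cohorts (e.g. colon vs rectal
adenocarcinoma, 20 tumours each) yields a protein × sample log2-intensity
matrix with 10–30% missing cells, most of them left-censored: low-abundance
proteins fall below the detection limit (MNAR), with a smaller
completely-at-random component (MCAR). One-size-fits-all imputation biases
every downstream statistic. ProteoSect routes each gap by mechanism and
carries the completed matrix through the rest of a comparative workflow:

* **Sectionalized imputation.** Proteins missing > 16 of 20 values in both
  groups are discarded; proteins missing > 18 in one group and < 8 in the
  other are kept as presence/absence candidates. A global threshold
  `T₁ = mean + 2·sd` (over all observed cells) splits the remaining gaps:
  cells of proteins whose observed mean exceeds T₁ are filled by
  k-nearest-neighbour proteins (k = 10, distance over jointly observed
  samples, 1/d weights); all others — the censored majority — are drawn
  from the per-sample down-shifted Gaussian
  `N(mean_s − 1.8·sd_s, (0.3·sd_s)²)`. Every cell keeps a provenance
  label, and `benchmarkImputation()` scores the scheme by RMSE against
  KNN-only and constant-fill baselines on synthetic data with known truth.
* **Gated differential screen.** Per protein: Brown–Forsythe Levene and
  per-group Shapiro–Wilk gates (at 0.1) select a pooled-variance Student
  t or a Mann–Whitney U test; calls require fold change
  `2^(meanA − meanB)` > 1.5 (up) or < 0.67 (down) at raw p < 0.05.
* **ssGSEA immune scoring.** Integrated running-sum enrichment per sample
  (exponent α = 0.25), signature-sum immune scores, group comparison,
  anti-/pro-tumor score correlation, row z-scoring, and Fisher-exact
  over-representation.
* **TOM hub detection.** Unsigned adjacency `|r|^5`, topological overlap
  `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, average-linkage cut
  of `1 − TOM` into two modules, intramodular TOM connectivity as
  centrality, PCA contribution values, and a consensus hub ranking.
* **Synthetic generator.** Two-group matrices with planted effects and a
  two-part MCAR + left-censoring mechanism, with full ground truth, so
  every stage is testable without any download.

The package is aimed at proteomics analysts who need a reproducible,
mechanism-aware alternative to single-method imputation for two-cohort
LFQ designs, with S4 containers built on `SummarizedExperiment`.

## Worked example

```r
library(ProteoSect)
x   <- simulateLfqExperiment(syntheticSpec(nProteins = 1000, seed = 42))
res <- sectionalizedImpute(x, seed = 42)
table(provenance(res))
#> downshift  observed
#>      5694     34306

deps <- screenDeps(res)
attr(deps, "counts")
#>   up down   ns
#>   49   22  929

bm <- benchmarkImputation(x, seeds = 1:3)
aggregate(rmse ~ method, bm, mean)
#>          method      rmse
#> 1      knn_only  3.846590
#> 2 sectionalized  3.522104
#> 3     zero_fill 11.139331
```

All 1,000 proteins survive filtering here; 5,694 censored gaps are filled
by down-shifted draws (none of this fixture's proteins sit above T₁, so
the KNN branch is idle — it serves the rare very-high-abundance
proteins). The screen calls 71 of 1,000 proteins (the generator planted
100 at a 2-fold shift, so roughly the well-powered half plus a few false
positives), and the sectionalized fill beats both baselines in RMSE on
the hidden truth. `runPipeline(config, outdir, input)` chains all stages
and writes six TSV tables plus a JSON manifest recording the
configuration, conventions and output digests.

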