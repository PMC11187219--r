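# crdsubtype

Circadian rhythm disruption (CRD) — the erosion of ~24 h gene-expression
programs — tracks the progression of coronary artery disease (CAD), but
most CAD transcriptome cohorts have no time-course component. `crdsubtype`
implements a workflow that quantifies CRD from static expression data and
uses it to define and validate molecular subtypes of CAD. It is aimed at
computational biologists working with plaque single-cell data and bulk CAD
cohorts (microarray or RNA-seq).

The workflow, end to end:

1. **Circadian gene discovery** — QC and log-normalize single-cell counts,
   select highly variable genes, build a WGCNA-style unsigned co-expression
   network (adjacency `|cor|^beta`, topological overlap), detect modules by
   static tree cut, and take the kME hub genes of the module most
   associated with vulnerable-plaque cells as the CAD circadian (CADCR)
   gene set.
2. **CRDscore** — per sample or cell,

   ```
   CRDscore = S_random − S_CADCR
   ```

   where `S_CADCR` is the mean expression of the CADCR genes and
   `S_random` the mean of 1000 random control genes sampled from the same
   expression bins (25 equal-occupancy bins, controls exclude the set).
   Positive scores mean the circadian genes sit below their matched
   background. Cells are called CRD-high above the 75th percentile; bulk
   samples above the median.
3. **Subtype discovery** — consensus K-means (Euclidean, k-means++, 80%
   subsampling) on the hub-gene signature for k = 2..6, with the optimal k
   chosen from the relative gain in area under the consensus CDF
   (delta-area elbow, threshold 0.1).
4. **Validation** — nearest template prediction: 50 signal-to-noise
   markers per subtype, cosine distance on per-sample z-scores (invariant
   to platform location/scale), permutation confidence from resampled gene
   sets with BH FDR.
5. **Downstream statistics** — Wilcoxon/Kruskal-Wallis score comparisons,
   stage-by-subtype composition with chi-square/Fisher routing,
   Kaplan-Meier curves and log-rank tests.

A bundled synthetic-data generator plants all of this structure —
co-expression modules, circadian suppression, four subtypes of sizes
124/93/87/132 (436 samples), stage skew and survival hazards — so the
whole pipeline runs against a known ground truth.

## Worked example

A reduced-scale discovery run (600 cells, 1,200 genes, four planted
subtypes of 40/30/30/40 samples, 60 consensus repetitions):

```r
library(crdsubtype)

cfg <- run_config(
  sim   = sim_config(n_cells = 600, n_genes = 1200,
                     n_samples_per_subtype = c(40, 30, 30, 40), seed = 1),
  n_hvg = 500, reps = 60, n_perm = 60, k_range = 2:5)
run <- run_discovery(cfg)
```

The run report (`run$report`) prints, among other things:

```
cells kept: 570 of 600
modules: 3  M1 = 1  AUC dev: 0.292
sc medians (stable, vulnerable): -0.467  0.511
chosen k: 4   subtype sizes: 41 30 32 37
bulk CRDscore medians: -0.474 0.752 0.166 -0.297
highest subtype: Type2   Kruskal-Wallis p: 6.4e-24
survival log-rank chisq: 13.3  p: 0.004
```

Reading this: 30/600 planted QC violators were removed; the module
designated M1 is the planted circadian module (its hubs are all `CRG`
genes), and vulnerable cells score ~1 unit higher than stable ones; the
consensus CDF elbow picks k = 4 and the recovered subtypes agree with the
planted ones (ARI 0.94); the cluster enriched for planted subtype 2 has
the highest median CRDscore and the worst survival — the planted
configuration of the study this package emulates.

Validation against independent cohorts:

```r
cohorts <- generate_validation_cohorts(cfg$sim, 4)
val <- run_validation(cfg, run$objects$templates, cohorts)
```

which reports per-cohort NTP accuracy (under optimal label matching),
the share of FDR < 0.05 calls, and the per-subtype score comparison.

## Package layout

- `R/synthetic.R` — generators with planted ground truth
- `R/preprocess.R` — QC, normalization, TPM, HVG, PCA, bin-matched scores
- `R/coexpression.R` — soft threshold, TOM, modules, eigengenes, kME, hubs
- `R/crdscore.R` — CRDscore, level calls, group comparisons
- `R/subtyping.R` — consensus K-means, CDF/delta-area, optimal k
- `R/ntp.R` — templates and nearest-template prediction
- `R/stats.R` — rank/contingency/survival tests, BH, composition tables
- `R/pipeline.R` — end-to-end orchestration and deterministic run reports
- `vignettes/crd-subtyping-methods.Rmd` — models, assumptions, design
  choices, and what the synthetic benchmarks do and do not show
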