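# rgcmarkers

Marker-gene discovery from small panels of single-cell transcriptomes, built
for the setting where a handful of hand-picked cells — parvalbumin-positive
(tdTomato-labelled) or electrophysiologically classified retinal ganglion
cells (RGCs) profiled on Affymetrix Mouse 430 2.0 arrays — must yield
candidate subset and subtype markers. The package is for transcriptomics
researchers working with small-n single-cell panels (microarray or
gene-level TPM), where large-n clustering toolkits do not apply and the
analysis has to stay transparent and auditable.

## What it computes

Given a probe-by-cell matrix of normalized signal `x`, cell annotations
(target vs comparison group, optional functional classes) and a
probe-to-symbol map, the pipeline runs:

* **Library QC** — cell passes iff every required gene is detected and no
  contaminant gene is (defaults: require *Sncg*; exclude *Rho*, *Glul*),
  with detection defined as `log2(x + 1) >= τ_det` (default `τ_det = 6`).
* **Variance filter** — per-probe sample SDs of log2 signal within each
  group; a two-component normal mixture
  `w₁·N(μ₁, σ₁²) + w₂·N(μ₂, σ₂²)` (μ₁ < μ₂) fitted by EM separates
  low-variance "noise" probes from informative ones; probes with
  `SD > 2.5` in **both** groups are retained.
* **Clustering** — UPGMA (average linkage) on the Pearson-correlation
  distance `d(i, j) = 1 − r(i, j)` over retained probes, with a
  deterministic tie rule, cut into `k = 4` clusters labelled by size.
* **Marker screens** — prevalence markers (detected in ≥ 7 of the target
  cells), cluster-enrichment by detection-prevalence contrast
  (`score = in-prevalence − out-prevalence`), seed-gene correlate screens
  at `r ≥ 0.53`, cross-dataset correlate intersection,
  functional-class-restricted genes, pairwise co-detection overlap, and
  gene-panel detection profiles.

A seeded synthetic-data generator (`sim_config()` / `generate_dataset()`)
plants exactly this structure — two cell groups, planted types with
type-restricted markers, a pan-class marker block, and a bimodal per-probe
SD distribution — so the whole pipeline is exercisable and testable with no
downloads. See the methods vignette
(`vignettes/marker-discovery.Rmd`) for the model, parameter rationale and
known statistical limits.

## Worked example

```r
library(rgcmarkers)

cfg <- pipeline_config(
  sim = sim_config(seed = 1), # study geometry: 9/4/1 target + 7 comparison
  seed_genes = "Sncg", seed = 1
)
res <- run_pipeline(cfg, quiet = TRUE)
res
#> <marker_pipeline>
#>   20000 probes x 21 cells; 2461 retained by SD filter (threshold 2.5)
#>   k = 4 clusters of sizes [9, 7, 4, 1]
#>   QC: 17 / 21 cells pass
#>   3094 majority-subset marker gene(s) at >= 7 cells
#>   Sncg correlates at r >= 0.53: 269 gene(s)

adjusted_rand_index(res$assignment, res$truth$cell_type)
#> [1] 1

res$mixture_target
#> <sd_mixture> two-component normal fit to 20000 SD values
#>   noise:       w = 0.806, mean = 0.772, sd = 0.280
#>   informative: w = 0.194, mean = 3.324, sd = 1.033
#>   logLik -16968.31 after 26 iteration(s), converged
```

Reading the output: of 20,000 probes, 2,461 survive the dual-group SD
filter (the mixture fit shows the planted 0.8 / 3.5 SD components, ~81%
noise weight); the k = 4 cut reproduces the planted cell types exactly
(adjusted Rand index 1): clusters of 9, 4 and 1 target cells plus the
7-cell comparison cluster. The QC gate passes all 14 target cells (the 4
flagged cells are comparison cells, which genuinely lack the required
pan-target gene — they are reported, never dropped). The *Sncg* correlate
list ranks the other planted pan markers at the top (r ≈ 0.74–0.84).

`write_pipeline_bundle()` (or `output_dir =` in the config) exports every
table as TSV, the dendrogram as Newick, and a JSON run manifest recording
every parameter in force.

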