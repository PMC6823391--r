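---
title: "Marker discovery from small single-cell panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery from small single-cell panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcmarkers)
```

# The problem

Retinal ganglion cells (RGCs) comprise more than forty functional subtypes,
and connecting a cell's physiology to its transcriptome requires profiling
very small panels of hand-picked cells — here, on the order of 14 to 29
single-cell libraries hybridized to Affymetrix Mouse 430 2.0 microarrays or
sequenced at low depth. At that scale the usual large-n single-cell toolkits
are a poor fit: there are no thousands of cells to regularize over, and the
analysis instead leans on a small set of transparent, auditable steps. This
package implements that analysis as a reusable pipeline:

1. **Library QC** — an in-silico gate that requires detection of a pan-RGC
   gene (*Sncg*) and absence of contaminant markers (*Rho* for rod
   photoreceptors, *Glul* for Mueller glia) in each cell library.
2. **Variance filter** — per-probe standard deviations are computed
   separately within the target cells (e.g. tdTomato+ RGCs) and within the
   comparison cells (non-RGCs); a two-component normal mixture fitted by EM
   describes the SD distribution, and probes whose SD exceeds a cutoff
   (default 2.5, log2 units) in *both* groups are retained.
3. **Clustering** — cells are clustered by average-linkage (UPGMA)
   agglomeration on the Pearson-correlation distance `1 - r` over the
   retained probes, and the tree is cut into `k` clusters (default 4).
4. **Marker screens** — prevalence-based subset markers (detected in at
   least 7 of the target cells, by default), per-cluster enrichment by
   detection-prevalence contrast, seed-gene correlate screens at a fixed
   correlation threshold (default 0.53), cross-dataset intersection of
   correlate lists, functional-class-restricted genes, pairwise
   co-detection overlap, and gene-panel detection profiles.

# Scales, transforms and conventions

Every statistical step operates on `log2(x + 1)`-transformed signal
(matrices already on a log2 scale bypass the transform). The 2.5 SD cutoff
is only plausible on a log scale — on linear MAS5 signal, which spans
hundreds to tens of thousands, it would retain essentially everything.
Conventions, all configurable, are:

* **Sample SDs** (denominator `n - 1`), and "above 2.5" read as a strict
  inequality.
* **Detection** is `log2(x + 1) >= tau_det`, with `tau_det = 6` by default
  (linear MAS5 signal of 63); the source analysis speaks of genes being
  "expressed" in a cell without defining a numeric rule, so the threshold is
  an explicit, tunable parameter here.
* **Distance** is `1 - r`, not `1 - |r|`: anti-correlated profiles are
  maximally distant, the standard choice for expression profiles.
* **Gene-level detection** is an OR over the gene's mapped probes —
  conservative for presence screening.
* A gene's **correlate score** is the Pearson correlation of its log2
  profile with the seed gene's profile across the dataset's cells; when a
  symbol maps to several probes, the highest-variance probe carries the
  seed profile and the best-scoring probe represents each correlate.

# The EM mixture fit

`fit_sd_mixture()` fits `w1*N(mu1, s1^2) + w2*N(mu2, s2^2)` to the SD values
by expectation-maximization, in log space for numerical stability.
Initialization is deterministic: the data are split at the median and
per-half moments seed the two components (degenerate halves fall back to
the extremes with a pooled spread), so identical inputs give identical
fits with no random restarts. Convergence is declared when the relative
log-likelihood change drops below `1e-8` (cap: 500 iterations); the
likelihood trace is retained so its monotonicity can be asserted rather
than assumed. Component SDs are floored at `1e-6` times the data spread to
prevent variance collapse, and components are always reported in
increasing-mean order. `suggest_threshold()` solves the weighted-density
crossing between the two means in closed form (quadratic; midpoint
fallback when no crossing lies between the means). The suggestion is
advisory — the operative cutoff stays the fixed 2.5 unless the user moves
it, mirroring the study's practice of fixing the cutoff by inspection.

# Clustering determinism

`average_linkage()` implements UPGMA with an explicit tie rule: among pairs
at the exact minimum average distance, the pair whose lexicographically
smallest member cell id is least (then the smaller partner id) merges
first. Cluster labels from `cut_tree()` are ordered by decreasing size,
ties again by smallest member id. These rules make the dendrogram and the
k-cut reproducible across platforms; average linkage itself guarantees
monotone merge heights. The test suite checks the implementation against a
brute-force agglomerator that re-averages the original distances every
round, and against `stats::hclust` on random inputs.

# What the synthetic generator emulates

`generate_dataset()` draws seeded probe-by-cell matrices with the
statistical structure the pipeline assumes, so every stage is exercisable
with no external data. Signals are drawn on the analysis scale
`v = log2(x + 1)` and emitted as `x = 2^v - 1` (floored at zero), so the
canonical transform recovers the planted log2 signal exactly.

* **Cells.** Planted types with configurable sizes, split into a target
  group and a comparison group. The default geometry mirrors the study:
  target types of 9, 4 and 1 cells plus one 7-cell comparison type.
* **Probe roles.** A fraction `frac_noise_probes` (default 0.82, matching
  a filter that keeps roughly 18% of probesets) are *noise* probes at a
  low baseline (log2 signal 4) with per-probe SD drawn from the low
  mixture component, `|N(0.8, 0.25)|`. The rest are *informative*:
  background-informative probes at an expressed baseline (log2 signal 8)
  with SD from the high component `|N(3.5, 0.6)|`; *type markers* (150 per
  type) at `detection_high = 14` in their type's cells and
  `detection_low = 4` elsewhere; and *pan markers* (50) on in every target
  cell. The first pan marker is named *Sncg* and two noise probes are
  named *Rho* and *Glul*, so the QC gate is exercisable out of the box.
* **Marker dispersion.** Target-type markers are tight within the profiled
  group (technical SD 0.4) but disperse at the informative-component mean
  (3.5) across the comparison cells. This emulates a real feature of the
  design being modelled: the comparison pool is a heterogeneous mix of
  cell classes (bipolar cells, amacrine cells, a cone photoreceptor), so
  genes that are cleanly on/off within the profiled class still vary at
  biological scale across the pool. It is also what makes a dual-group SD
  filter workable at all: a marker that were merely flat-plus-technical-
  noise in the 7 comparison cells would have comparison-group SD far below
  2.5 and every type marker would be filtered out, leaving no type signal
  for the clustering. Pan markers and comparison-type markers carry
  informative-scale dispersion everywhere for the same reason — it lets
  them clear the filter in both groups and lets the comparison cells
  cohere into one cluster at the k = 4 cut.

Features of real microarray data the generator does **not** emulate:
probe-level hybridization artifacts, array-wide intensity drift or batch
structure (noise is independent across probes and cells), probe-set
redundancy per gene (each synthetic probe has its own symbol), dropout
structure of low-input libraries, and any correlation between expression
level and variance beyond the two planted components. Passing tests on
synthetic data therefore demonstrate the correctness and determinism of
the pipeline's logic under its own assumptions — not that those
assumptions hold for any particular deposited dataset.

# Validation geometry and known statistical limits

Two properties deserve explicit framing, both consequences of small cell
counts rather than implementation choices.

* **Filter separation is validated on 60 + 60 cells.** With only 7
  comparison cells, a sample SD has 6 degrees of freedom and falls below
  2.5 about 20% of the time even when the population SD is 3.5
  (chi-square tail), so no filter can keep 99% of informative probes at
  that group size. The filter-recovery check therefore uses 60 cells per
  group — where the 99% / 1% separation is a property of the method, not
  of sampling luck — while the pipeline-recovery check keeps the study's
  own 14 + 7 geometry.
* **Chance correlates are unavoidable at 21 cells.** Under the null, a
  Pearson correlation over 21 cells has spread `1/sqrt(20) = 0.22`, so a
  fixed cutoff of 0.53 admits roughly 0.7% of null probes; over ~16,000
  noise probes that is on the order of a hundred chance correlates. The
  correlate screen deliberately runs over all probes (the study screened
  full transcriptomes) and applies no multiple-testing control (the study
  used fixed correlation cutoffs, not p-values), so its output should be
  read as a candidate list for downstream validation — exactly how the
  study used in situ hybridization — not as a controlled discovery set.
  Restricting the screen to variance-filter survivors (pass the retained
  probe set via the matrix argument) suppresses chance correlates at the
  cost of dropping genes whose comparison-group SD fluctuated below the
  cutoff. The acceptance suite keeps the all-probe screen and asserts the
  zero-chance-correlate expectation as stated; that expectation fails at
  this cell count, and the computed count is reported honestly by
  `scripts/acceptance.R`.

# Problem sizes

The shipped checks use 20,000 probes (the full 45,101-probeset geometry is
supported but adds nothing statistically), 5,000 draws for mixture
recovery, 200 random distance matrices of up to 8 leaves for the linkage
oracle, and 100 seeded pipeline runs at the 9/4/1 + 7 geometry for
planted-partition recovery. These sizes were chosen so the whole suite
exercises every stage at full fidelity while remaining quick to run on a
laptop.

# Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(seed = 1),
  seed_genes = "Sncg",
  output_dir = "report"
)
res <- run_pipeline(cfg)
summary(res)

# planted-partition agreement
adjusted_rand_index(res$assignment, res$truth$cell_type)

# the tree, the cut and the screens
export_newick(res$dendrogram)
res$markers[res$markers$category == "majority_subset", ][1:5, ]
res$correlates$Sncg
```

For file-based runs, point `pipeline_config()` at a tab-delimited
series-matrix-style expression table, a cell annotation table
(`cell_id`, `dataset`, `group`, optional `functional_class`) and a
two-column probe-to-symbol map; `read_matrix()` documents the dialect.

# Limitations

* The pipeline consumes already-normalized matrices; MAS5 summarization,
  CEL parsing, read alignment and quantification are out of scope.
* `k` is an explicit input; the package does not choose the number of
  clusters.
* With panels of one or two dozen cells, clustering is fragile by nature —
  the study itself found one cell that refused to join either main
  cluster — and marker calls from such panels are hypotheses to validate,
  not endpoints.
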