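---
title: "Valley-Ridge scoring of cell plastic potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valley-Ridge scoring of cell plastic potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valleyridge)
```

## The problem and the model

Differentiation hierarchies in single-cell data are usually summarized by a
trajectory, but the question "which cluster is the *origin*?" needs a
per-cluster potential, not a path. This package scores that potential on a
Waddington-landscape analogy. Three observations motivate the score:

1. **Entropy.** Cells at the top of a hierarchy express broad, promiscuous
   programs dominated by highly connected (hub) genes of the protein
   interaction network; committed cells express narrow marker programs.
   The CCAT statistic — the Pearson correlation between a cell's
   normalized log expression and gene-wise network degree — captures this
   with a single pass over the matrix and is bounded in [-1, 1]. Cells
   whose expression is constant over the shared gene universe have no
   defined correlation; they are reported `NA` and excluded from medians
   rather than imputed as 0, which would drag cluster medians toward the
   middle.

2. **Velocity.** Cells at attractor states have balanced unspliced/spliced
   abundances, so the residual `v = u − γs` of a steady-state fit is short;
   cells in transit have long residuals. We fit `γ` per gene by least
   squares through the origin on the cells in the top `extreme_quantile`
   (default 5 %) of `s + u` — the regime where the steady-state assumption
   is most defensible — and exclude genes with fewer than `min_counts`
   (default 10) total counts or no spliced signal in the selected cells.
   The per-cell length is the L2 norm over fitted genes, in gene space.
   Dynamical and negative-binomial velocity likelihoods exist, but only
   the *length* enters the score, and the steady-state residual preserves
   the one property the score consumes: short at attractors, long in
   transit. Lengths in embedding projection are a plausible alternative;
   gene space was chosen because it needs no extra projection choice.

3. **Geometry.** In a trajectory-preserving embedding (PHATE here), root
   clusters feed their neighbors: their cells spread from the cluster
   core along outgoing paths. Within each (sample, cluster) group we take
   the density medoid — the cell maximizing the inverse mean distance to
   its k nearest neighbors — as the core, and use the min-max scaled
   Euclidean distance to it. The neighborhood size adapts to the group:
   `k = max(5, round(0.05 n))`, capped at `n − 1`. The exact centrality
   recipe used upstream of this package's lineage is defined in a
   protocol we do not restate; the medoid-of-density definition above is
   this package's declared operationalization, and it should not be
   assumed to match that protocol in every detail. Medoid ties are broken
   by lowest cell id so results are deterministic.

Per sample-cluster these aggregate as

* `Valley = median(CCAT)` (raw, unscaled — the component already lives in
  [-1, 1]),
* `Ridge = median(scale01(1/L)) × median(scaled centrality distance)`,
* `VR = w_V · Valley + w_R · Ridge` with default weights 0.9 / 0.1.

Inverse lengths are infinite for cells with `L = 0`; they are capped at
the largest finite inverse in the scaling scope before scaling, so a
handful of perfectly steady cells cannot collapse the scale. The scope
defaults to *global* (all cells of all samples scaled together) so that VR
values are comparable across the two conditions being contrasted; a
per-sample scope is available when the samples' velocity scales are not
comparable (e.g. different chemistry). The Ridge sentence "product of the
median scaled inverse velocities and the scaled cell centrality distances"
is ambiguous between a product of medians and a median of products; the
product of medians follows the phrase order and is the default, with
`ridge_aggregation = "median_of_products"` exposed for the alternative.
With nonnegative components, `Ridge ∈ [0, 1]` and `VR ∈ [−0.9, 1]` under
the default weights.

Apexes are clusters ranked by VR within a sample; `ΔVR` is the per-shared-
cluster difference between the two samples. Whether a cross-sample
"entropy shift" should difference CCAT medians or VR scores is not settled;
`rank_apexes()` reports the VR difference and the Valley column makes the
CCAT-only difference a one-liner, so both readings are available.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_genes_per_cell` | 100 | genes | cells expressing fewer genes are ambient/debris; threshold is strict (`< 100` removed) |
| `max_mito_fraction` | 0.20 | fraction | above this, likely stressed/dying cells |
| `min_cells_per_gene` | 20 | cells | genes below are too sparse to rank or fit |
| `target_sum` | 10 000 | counts | ecosystem-standard depth target before `log1p` |
| `extreme_quantile` | 0.05 | fraction | steady-state fit regime |
| `min_counts` | 10 | counts | minimum evidence to fit a gene's γ |
| `knn` | `"auto"` | cells | `max(5, 0.05 n)` per group |
| `w_valley`, `w_ridge` | 0.9, 0.1 | — | entropy dominates; geometry breaks ties |
| `rho_min` | 0.5 | correlation | strict spatial retention threshold |
| `n_bins`, `n_ctrl_per_bin` | 25, 50 | — | module-score control matching |

QC operational details the thresholds do not pin down: "expressed" means
count > 0 on the spliced layer (the conventional expression layer;
unspliced is subset by the same masks), and the mitochondrial fraction is
mito counts over total counts per cell, with mito genes identified by the
`mt-` name prefix.

## What the simulator emulates — and what it does not

`simulate_tree()` generates the statistical structure the score assumes,
so that ground truth exists by construction:

* **Connectome**: heavy-tailed gamma degrees with a `hub_fraction = 0.1`
  of genes boosted 8–20×, mimicking scale-free PPI degree distributions.
* **Programs**: root cells draw means `∝ degree^α` (α = 1), leaves draw
  hub-free marker programs; interior clusters interpolate by tree depth.
  This makes CCAT decrease along the tree by construction.
* **Kinetics**: per-gene splicing ratios γ ~ U(0.2, 1); steady cells have
  `E[u] = 0.3 γ E[s]` while the `transitional_frac = 0.3` of each
  non-root cluster's cells carry a 4× unspliced excess and sit midway to
  the parent cluster in the embedding. Velocity lengths are therefore
  bimodal with known flags.
* **Counts**: negative binomial with dispersion 0.5 (NB size 2), library
  scale ~2000 — realistic overdispersion for droplet data.
* **Design**: two samples over a 5-cluster tree rooted at `c1`, plus a
  KO-unique root-like cluster `c6`, 200 cells per cluster (1000 / 1200
  cells). These sizes keep the full 20-seed recovery study comfortably
  within a coffee break on one core while leaving per-cluster medians
  stable.

`simulate_spatial()` reuses the cluster programs on a 100-gene subpanel
and samples each unit's identity from its clone's mixing proportions —
enough to exercise Spearman transfer and clone heterogeneity end to end.

Not emulated: batch effects, doublets, ambient RNA, regulatory-network
dynamics, realistic embedding geometry (clusters are Gaussian blobs at
tree-node positions), and any coupling between velocity and embedding
direction. Passing the recovery tests therefore shows the scoring is
*internally consistent* — it finds roots whose entropy, kinetics and
geometry behave as modeled — not that it is robust to the failure modes
of real data.

## Numerical choices and degenerate inputs

* Min-max scaling of a constant vector returns all zeros (not NaN); a
  cluster whose velocity lengths are all equal in scope thus gets Ridge 0.
* Even-sized medians use the mean of the central pair (`stats::median`).
* Spearman uses average ranks for ties; argmax ties in label transfer go
  to the lowest cluster id; units with constant profiles get `NA` and are
  never retained. Retention is strict (`rho > rho_min`), so a unit at
  exactly 0.5 is unassigned.
* The module score bins genes by average-rank of mean expression into
  equal-width bins and samples `min(n_ctrl_per_bin, bin size)` controls
  per occupied bin without replacement, under the configured seed.
  Cell-cycle calls: G1 if both S and G2M scores are negative, otherwise
  the larger score wins with ties going to S.
* All simulation and sampling entry points take explicit seeds and restore
  the caller's RNG state on exit.

## Scope and limitations

Clustering, embedding, batch correction and ortholog mapping are inputs,
not features: the package consumes labels, coordinates and a user-supplied
gene-degree (and, if needed, ortholog) table. Regressing the mitochondrial
fraction out of expression before scoring is deliberately not performed.
The landscape grid is the numeric surface only; rendering is left to
external tools. Matrix I/O is MatrixMarket + TSV sidecars; an HDF5
container is not read — export to MTX first. The Valley component
dominates VR by an order of magnitude under the default weights, so apex
calls are driven by entropy; the Ridge mostly resolves near-ties, and
conclusions that hinge on Ridge alone warrant a sensitivity check over
`w_ridge`.
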