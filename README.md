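# valleyridge

Which clusters in a single-cell RNA-seq experiment act as the *origins* of a
lineage — the populations with the highest cell plastic potential? This
package answers that question on a Waddington-landscape analogy: clusters
are scored so that lineage roots sit at landscape **apexes**, and two
conditions (e.g. a wild-type and a knock-out tumor) can be compared apex by
apex. It is aimed at analysts who already have clustered, embedded
(e.g. PHATE) single-cell data with spliced/unspliced counts and want a
transparent, testable scoring of root potential, plus the standard
companions: cluster-composition comparison, gene-set module scores and
cell-cycle calls, and Spearman label transfer onto targeted spatial panels.

## The score

For every sample *s* and cluster *c*, three per-cell signals are aggregated:

- **CCAT entropy** `r_i = cor(x_i, d)` — the Pearson correlation between
  cell *i*'s normalized log expression `x_i` and the connectome degree `d`
  of the same genes (a fast surrogate for signaling entropy /
  differentiation potency).
- **RNA-velocity length** `L_i = || u_i − γ ⊙ s_i ||₂`, where the per-gene
  splicing ratio `γ_j = Σ u·s / Σ s²` is fitted by least squares through
  the origin on the cells in the top 5 % of spliced+unspliced abundance.
  `L` is small near attractor (steady) states and large in transit.
- **Centrality distance** `D_i` — the Euclidean distance from cell *i* to
  its cluster's density medoid in the embedding (kNN density proxy,
  k = max(5, 0.05·n)), min-max scaled within the (sample, cluster) group.

These combine into

```
Valley(s,c) = median_i∈(s,c) r_i
Ridge(s,c)  = median_i∈(s,c) scale01(1/L_i) × median_i∈(s,c) D_i
VR(s,c)     = 0.9 · Valley + 0.1 · Ridge
```

with `scale01` a min-max scaling over all cells (inverse lengths capped at
the largest finite value first). Clusters ranked by VR give the apex order;
`ΔVR = VR_sample2 − VR_sample1` localizes plasticity gains per shared
cluster, and `landscape_grid()` emits the kernel-smoothed height surface a
3D renderer would display.

## Worked example

The bundled simulator generates a two-sample branching trajectory with
known roots: five shared clusters (`c1` the root; `c1→c2→c3`, `c2→c4`,
`c3→c5`) plus a KO-unique root-like cluster `c6`, 200 cells each,
negative-binomial counts.

```r
library(valleyridge)
sim <- simulate_tree(sim_config(seed = 1))
res <- cpp_pipeline(sim$counts, sim$cells, sim$degrees)
res$vr
#>    sample_id cluster_id n_cells      valley      ridge          vr
#> 1         KO         c1     200  0.54911125 0.14792928 0.508993050
#> 2         KO         c2     200  0.46850542 0.12276792 0.433931668
#> 3         KO         c3     200  0.38604809 0.09296823 0.356740106
#> 4         KO         c4     200  0.38909355 0.08782928 0.358967121
#> 5         KO         c5     200 -0.00224482 0.05297972 0.003277635
#> 6         KO         c6     200  0.55559351 0.16581634 0.516615797
#> 7         WT         c1     200  0.54976552 0.19598086 0.514387053
#> 8         WT         c2     200  0.47498611 0.11328815 0.438816317
#> 9         WT         c3     200  0.38425153 0.09134571 0.354960952
#> 10        WT         c4     200  0.38920929 0.09038612 0.359326969
#> 11        WT         c5     200 -0.00105459 0.06182864 0.005233733
res$apexes
#> $KO
#> [1] "c6" "c1" "c2" "c4" "c3" "c5"
#> $WT
#> [1] "c1" "c2" "c4" "c3" "c5"
```

Reading the table: the Valley column tracks how hub-correlated (entropic)
each cluster's transcriptome is — highest for the true roots `c1` and `c6`,
near zero for the terminal cluster `c5`. The VR ranking therefore places
`c1` at the wild-type apex and recovers both `c1` and the KO-unique `c6`
as apexes of the KO sample, mirroring how a condition that unlocks
plasticity surfaces new root clusters. Across 20 simulation seeds the true
root tops the ranking in 20/20 runs (asserted in the test suite).

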