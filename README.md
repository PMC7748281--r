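# focal3d

Grid-based density clustering for 3D single-molecule localization microscopy
(SMLM), with objective parameter selection.

SMLM experiments (PALM, dSTORM, PAINT) yield tables of hundreds of thousands
of estimated fluorophore coordinates. Identifying nanoscale clusters —
protein assemblies, nuclear pore complexes, membrane domains — in these point
clouds is usually done with density-based clustering, but the workhorse
(DBSCAN) requires hand-tuning two parameters and scales as
*n*<sub>l</sub> log *n*<sub>l</sub>. **focal3d** implements the FOCAL3D
algorithm: localizations are binned onto a cubic grid of spacing Δ, each
occupied voxel's count is replaced by its 3×3×3 neighbourhood sum, voxels at
or above a density threshold *minL* become core, occupied sub-threshold face
neighbours become border, and connected candidates of at least *minC* voxels
are the clusters. Working on the grid makes the run time linear in the
number of localizations, and — unlike DBSCAN — the parameters can be chosen
objectively:

* ***minL**\** is the lowest threshold at which clustering a
  complete-spatial-randomness surrogate of the data (same point count,
  uniform in the same volume) returns **zero** clusters;
* **Δ\* and *minC*\*** are read off clusters-vs-*minC* scans: near a good
  grid size the detected count develops a plateau — a region insensitive to
  *minC* — and parameters on that plateau give the best clustering.

The package also ships the synthetic SMLM benchmark generator used to
validate the method (spherical clusters, Poisson dye counts, geometric blink
counts with mean 10, anisotropic 10/20 nm localization scatter, uniform
background noise set by a dimensionless level ζ) and the validation metrics:
precision/recall/F1 against ground truth, the cluster-level silhouette score
S<sub>C</sub> = (d̄<sub>NN</sub> − d̄<sub>C</sub>)/d̄<sub>NN</sub>,
convex-hull effective cluster radii, and 3D Ripley K/L/H curves.

## Worked example

Regenerate the 80 nm benchmark (100 spherical clusters of radius 80 ± 16 nm
in 100 µm³, noise level ζ = 0.01), select parameters objectively, cluster,
and score against ground truth:

```r
library(focal3d)

sim <- simulate_smlm(smlm_preset("80nm"), zeta = 0.01, seed = 1)
sim
#> Synthetic SMLM dataset
#>   clusters: 100 (1 population), zeta = 0.01
#>   localizations: 20275 clustered + 83263 noise = 103538
#>   volume: 4642 x 4642 x 4642 nm (seed 1)

scan <- focal_scan(sim$locs, delta = 40, minC = seq(2, 80, 2), seed = 2)
plateau <- find_plateau(scan)
plateau
#> FOCAL3D plateau report (rel_tol = 0.02 )
#>   delta minC_start minC_end length n_clusters minL_star
#> 1    40          8       22      8        101         8
#>   recommended: delta* = 40 nm, minC* = 8, minL* = 8 -> 101 clusters [ok]

fit <- focal3d(sim$locs, delta = plateau$delta_star,
               minL = plateau$minL_star, minC = plateau$minC_star)
fit
#> FOCAL3D clustering
#>   parameters: delta = 40 nm, minL = 8, minC = 8
#>   grid: 118 x 118 x 119 voxels
#>   localizations: 103538 (20824 clustered, 82714 noise)
#>   clusters: 101

confusion_report(fit$labels, sim$truth)
#> confusion: TP 20132  FP 692  FN 143  TN 82571
#> P = 0.9668  R = 0.9929  F1 = 0.9797

silhouette_score(fit)
#> silhouette S_C = 0.867  (d_NN = 630.3 nm, d_C = 83.9 nm; intra = pairwise)
```

The plateau sits at 101 detected clusters against the 100 simulated; the
clustering recovers 99.3% of the clustered localizations (recall) with 96.7%
precision — the residual false positives are background points that happen
to fall inside cluster voxels, which no density method can distinguish. The
mean convex-hull effective radius of the detected clusters,
`mean(cluster_radii(fit)$effective_radius)`, comes out at 80.9 nm against the
generative 80 nm.

`plot(scan, target = 100)` draws the clusters-vs-minC curves;
`ripley_k(sim$locs, seq(10, 400, 10), box = sim$box)` estimates the cluster
length scale (H peaks near 100 nm here), a good way to bracket the Δ search.

A thin command-line interface over the same functions is installed at
`inst/cli/focal3d.R` with subcommands `simulate`, `cluster`, `optimize`,
`metrics` and `ripley`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/focal3d.R", package="focal3d"))')" \
  cluster --input t.csv --delta 40 --minC 10 --out labeled.csv
```

Localization tables are CSV/TSV with auto-detected `x,y,z` or
ThunderSTORM-style `"x [nm]"` headers (units nm); output is the input table
plus a `cluster_id` column (−1 = noise) and an optional per-cluster summary.

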