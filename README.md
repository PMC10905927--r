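# threewayclust

Model-based clustering of three-way RNA-seq time-course data: genes
measured over time under several experimental conditions (strains,
knock-outs, process settings). The package is aimed at analysts who want
groups of co-expressed genes that respect the full gene × time ×
experiment structure instead of flattening the experiments away.

## The method

The workflow has four steps:

1. **Normalised expression profiles.** Counts are depth-corrected with
   median-of-ratios size factors *s* and each gene × experiment time
   course becomes a unit-sum profile
   *p<sub>itj</sub> = (x<sub>itj</sub>/s<sub>tj</sub> + c) /
   (Σ<sub>t</sub> x<sub>itj</sub>/s<sub>tj</sub> + cT)*,
   computed per replicate and then averaged.
2. **Log-ratio transform.** Profiles are compositional, so they are
   mapped to Euclidean space with the additive log-ratio transform using
   the first time point T0 as reference — coordinates are log fold
   changes relative to T0 (clr and pivot-basis ilr are also provided).
3. **Matrix-variate Gaussian mixtures.** Each gene is a J × 𝒯 matrix
   (experiments × transformed time points, 𝒯 = T − 1) modelled by a
   K-component mixture with matrix-normal components:
   vec(Y) ~ N(vec(M<sub>k</sub>), Ψ<sub>k</sub> ⊗ Σ<sub>k</sub>), with a
   component-specific *diagonal* experiment covariance Σ<sub>k</sub> and
   a time *correlation* Ψ<sub>k</sub> — general, or AR1
   (ρ<sub>k</sub><sup>|t−s|</sup>) fitted as a refinement of the general
   solution. Estimation is by a seeded multi-start EM; K is chosen by
   ICL (BIC also reported), smaller is better.
4. **Diagnostics.** Density-based silhouette information (dbsi, the
   normalised log ratio of the top two posteriors, in [−1, 1]), the dbsi
   information plot, and the *cluster map* — dbsi against the scaled
   distance to the back-transformed cluster centre in profile space,
   faceted by cluster with convex hulls. Partitions are compared by
   adjusted Rand index and contingency tables.

A seeded simulation harness (`run_simulation_study()`) compares the
three-way approach against a flattened two-way Gaussian mixture and
k-means with silhouette-based selection of K.

## Worked example

Simulate a synthetic count dataset (300 genes, 6 time points, 2
experiments, 3 replicates, 4 generating clusters), run the four steps,
and select K:

```r
library(threewayclust)
sc <- simulate_counts(n = 300, T = 6, J = 2, R = 3,
                      model = study_generator(K = 4, Tc = 5), seed = 3)
ct  <- count_tensor(sc$counts, sc$meta)
P   <- average_replicates(normalized_profiles(ct))
Y   <- profiles_to_alr(P)
sel <- matmix_select(Y, 1:6, column_structure = "ar1", seed = 1,
                     n_starts = 2)
sel
#> Model selection over K in {1, 2, 3, 4, 5, 6} by ICL (ar1 time correlation)
#>  K   loglik nu     bic     icl bic_conventional converged
#>  1 -2908.57 13 9.81881 9.81881          5891.29      TRUE
#>  2 -2040.69 27 7.05898 7.05977          4235.39      TRUE
#>  3 -1270.19 41 4.62373 4.62394          2774.24      TRUE
#>  4 -1032.28 55 3.96379 3.96379          2378.27      TRUE
#>  5 -1017.66 69 4.04814 4.14329          2428.88      TRUE
#>  6 -1004.11 83 4.13605 4.28394          2481.63      TRUE
#> selected: K = 4
adjusted_rand(sc$labels, sel$best$labels)
#> [1] 1
```

ICL drops steeply up to the true K = 4 and rises afterwards (the entropy
term punishing the blurred 5- and 6-component splits), and the MAP
partition recovers the generating labels exactly. Diagnostics:

```r
d  <- dbsi(sel$best)                       # separation, transformed space
cd <- center_distance(P, sel$best)         # compactness, profile space
plot_dbsi(d)
plot_cluster_map(cluster_map_data(d, cd$distance))
```

File-based runs go through `run_config()` + `run_preprocess()` /
`run_cluster()` / `run_evaluate()`, which write TSV/JSON/PNG artifacts
and a YAML config snapshot into the output directory.

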