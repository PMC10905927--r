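---
title: "Clustering three-way RNA-seq time courses with matrix-variate Gaussian mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering three-way RNA-seq time courses with matrix-variate Gaussian mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Time-course RNA-seq experiments run under several conditions — strains,
knock-outs, process settings — produce a three-way data structure: genes
× time points × experiments, with a handful of biological replicates per
sample. The goal served by this package is to find groups of genes that
are co-expressed *over time and across experiments simultaneously*,
rather than flattening the experiment dimension away. The workflow has
four steps.

## Step 1 — normalised expression profiles

Counts are corrected for sequencing depth with per-sample
median-of-ratios size factors (`estimate_size_factors()`; the factor of a
sample is the median over all-positive genes of the count divided by the
gene's across-sample geometric mean, rescaled so the factors have
geometric mean exactly 1 — the package's fixed convention, since only
relative depths matter). For every gene $i$, experiment $j$ and
replicate, the time course is turned into a *normalised expression
profile*

$$p_{itj} = \frac{x_{itj}/s_{tj} + c}{\sum_{t=1}^{T} x_{itj}/s_{tj} + cT},$$

a strictly positive vector over the $T$ time points summing to one.
Profiles are computed per replicate and then averaged
(`average_replicates()`); size factors are estimated per sample — i.e.
per (time, experiment, replicate) — because depth varies at the sample
level, and means of unit-sum vectors are again unit-sum. The pseudo-count
defaults to $c = 1$; `pseudo = "half-min"` (half the smallest positive
depth-corrected count) is available. Genes with no reads in an experiment
are kept and get a uniform profile: the formula is well defined there and
removal is a filtering decision, which belongs to the external
differential-expression step (the package only applies a supplied gene
list via `filter_genes()`).

Note that exact invariance of the profiles under rescaling one sample's
counts holds for $c = 0$; with a positive pseudo-count it is approximate,
which is the price of zero handling.

## Step 2 — log-ratio transformation

A profile carries only relative information, so it is treated as
compositional data on the simplex. The additive log-ratio transform with
the first time point as reference,

$$\mathrm{alr}(p)_t = \ln(p_t / p_{T_0}), \qquad t \ne T_0,$$

maps each gene × experiment profile to $\mathcal{T} = T - 1$
unconstrained coordinates interpretable as log fold changes relative to
T0 (`profiles_to_alr()`). The centred (clr) and isometric (ilr, pivot
basis) transforms are provided for completeness and for checking the
geometry — ilr is an isometry, clr is rank-deficient — but the workflow
uses alr because its coordinates are directly interpretable in a time
course. Parts below `1e-300` are rejected rather than clamped; rounded
zeros should be handled explicitly with `zero_replace()` or the
pseudo-count of Step 1 (the default pipeline handles zeros only at the
profile stage).

## Step 3 — mixtures of matrix-variate Gaussians

After transformation every gene is a $J \times \mathcal{T}$ matrix
(experiments × time coordinates). `matmix()` fits a $K$-component
mixture whose components are matrix-normal,

$$\mathrm{vec}(Y) \sim N\!\big(\mathrm{vec}(M_k),\; \Psi_k \otimes \Sigma_k\big),$$

with a free mean matrix $M_k$, a **diagonal, heteroscedastic** experiment
covariance $\Sigma_k$ (experiments are designed to be independent, but
clusters may have different volumes per experiment, so both noise
clusters and tight clusters can coexist) and a time **correlation**
matrix $\Psi_k$ — either a general correlation or the AR1 restriction
$\Psi_k[t,s] = \rho_k^{|t-s|}$, which encodes conditional independence
beyond lag one with a single parameter. Fixing $\Psi_k$'s diagonal at one
resolves the scale non-identifiability of a Kronecker product; all scale
lives in $\Sigma_k$. The separability pays off in parameter count: for
$J = 2$, $\mathcal{T} = 5$ the two covariance factors carry
$2\cdot3/2 + 5\cdot6/2 = 18$ parameters against $10\cdot11/2 = 55$ for an
unrestricted covariance of the vectorised observation
(`n_cov_params()`).

### EM details and numerical choices

* **E step**: posteriors via log-sum-exp; densities evaluated through
  Cholesky factors.
* **M step**: sizes and means in closed form; the covariance pair by one
  flip-flop sweep — $\sigma^2_{kj}$ given $\Psi_k$ (exact conditional
  maximiser), then the column scatter is rescaled to unit diagonal with
  the removed scale (geometric mean of the scatter's diagonal)
  transferred into $\Sigma_k$. The unit-diagonal projection is not an
  exact conditional maximisation, so it is *guarded*: the candidate is
  kept only when it improves the expected complete-data log-likelihood,
  making the algorithm a monotone generalized EM. Under AR1 the update of
  $\rho_k$ is a bounded one-dimensional search on $(-0.999, 0.999)$
  (tolerance `1e-6`) using the closed-form tridiagonal inverse of the AR1
  matrix, which *is* exact, so no guard is needed there.
* **Initialisation**: the first start uses k-means on the vectorised
  data, further starts use random hard assignments; the best of
  `n_starts` (default 10) final log-likelihoods wins. All randomness runs
  through `set.seed(seed)`.
* **Safeguards**: variance floor `1e-10` on the $\Sigma_k$ diagonals, a
  `1e-10` ridge on $\Psi_k$ before inversion, and a start is abandoned
  and redrawn when a component's expected size falls below
  $J + \mathcal{T}$ (up to twice the start budget); if every start
  collapses the fit errors rather than returning a degenerate model.
* **Convergence**: relative log-likelihood change below `tol`
  (default `1e-8`), capped at `max_iter` (default 500).

The AR1 model is fitted as a *refinement*: `matmix_select()` with
`column_structure = "ar1"` first fits the general-correlation model at
each $K$ and uses that solution to initialise the restricted EM
(`refit_ar1()`, starting $\rho_k$ from the average lag-one entry of the
fitted $\Psi_k$). Since AR1 correlations are nested in general ones, the
refit's log-likelihood should not exceed the full fit's, which the test
suite asserts.

### Choosing K

Model selection uses, per observation,

$$\mathrm{BIC}(K) = -\ell/n + \frac{\nu_K}{2n}\ln n, \qquad
  \mathrm{ICL}(K) = \mathrm{BIC}(K) + \mathrm{entropy},$$

with $\ell$ the total log-likelihood, $\nu_K$ the free-parameter count
($KJ\mathcal{T}$ means, $K-1$ sizes, $KJ$ variances, and per component
$\mathcal{T}(\mathcal{T}-1)/2$ correlations or one AR1 parameter) and
entropy $-\tfrac1n\sum_{ik}\tau_{ik}\ln\tau_{ik}$; smaller is better. The
per-observation scaling was chosen deliberately: it makes the printed
formula self-consistent while ranking candidate models identically to the
conventional $-2\ell + \nu_K \ln n$, which `matmix_criteria()` reports
alongside so either convention can be cross-checked. ICL is the default
criterion because its entropy term rewards well-separated partitions —
the analysis goal is small, compact, interpretable gene groups rather
than the "true" $K$.

## Step 4 — diagnostics

With posteriors winsorized to $[10^{-5}, 1-10^{-5}]$ (exactly the fixed
default; configurable), the **density-based silhouette information** of
gene $i$ is the log ratio of its top two posteriors, normalised by the
largest absolute log ratio in the dataset, so values lie in $[-1, 1]$ and
the best-separated gene sits at $\pm 1$ (`dbsi()`). The **dbsi
information plot** shows the values per cluster in decreasing order;
clusters are ordered by average classic silhouette width when one is
supplied (the plot's convention) and by average dbsi otherwise — both
orderings are exposed because either can be preferred, and the default
used by `run_evaluate()` is the silhouette ordering. The **cluster map**
(`cluster_map_data()`) plots dbsi against the scaled Euclidean distance
between each gene's profile and its cluster centre mapped back to the
original profile space over all $T$ time points (`center_distance()`;
the alr-space model lives in $\mathcal{T}$ dimensions, the distance
deliberately in $T$), faceted by cluster with convex hulls: the ideal
cluster occupies the top-left corner — separated *and* compact. Classic
silhouettes define singleton clusters as 0. Partitions are compared with
the adjusted Rand index and contingency tables; the degenerate ARI case
of two all-in-one partitions is defined as 1 (the adjustment formula is
0/0 there, but the partitions are identical).

# The synthetic-data generators, and what passing tests show

`simplex_clusters()` draws Gaussian clusters in two-dimensional log-ratio
space and maps them to the three-part simplex — it illustrates (and lets
tests verify) how the transform reshapes cluster volumes. Its default use
in examples reproduces the qualitative phenomena (corner-concentrated
clusters, a mid-simplex cluster that is compact in Euclidean space); it
is illustrative, not a replication of any particular dataset.

`simulate.matmix()` draws from a mixture via $Y = M_k + \Sigma_k^{1/2} Z
B_k$ with $B_k^\top B_k = \Psi_k$, giving exactly the Kronecker
covariance; tests check empirical moments at Monte-Carlo scale.

`study_generator()` is a *synthetic stand-in* for a mixture estimated on
real data: $K = 10$ components on $2 \times 5$ matrices, component sizes
spanning 26–181 of 769 genes, smooth random-walk mean time courses with
the second experiment's row a perturbation of the first, log-normal
experiment variances around 0.12, and AR1 autocorrelations drawn from
(0.3, 0.8). These values were fixed once as a realistic regime for
log-ratio expression data: coordinate-level noise SD around 0.35 against
mean curves moving by order one per step gives moderately overlapping
clusters. `simulate_counts()` wraps it into a raw count dataset
(mixture profiles × log-normal gene abundance × log-normal sample depth,
Poisson counts) so the whole pipeline, including normalisation, can be
exercised from the count stage.

What the generators do *not* emulate: over-dispersion beyond Poisson,
gene-length effects, outlier genes with non-Gaussian log-ratio profiles,
and dependence between genes. Passing tests therefore demonstrate
correctness of the algorithms under the model's own assumptions, not
performance guarantees on any real dataset.

# The simulation study

`run_simulation_study()` compares four methods on replicate datasets
drawn from the generator: three-way clustering with full and with AR1
time correlation (sharing one EM pass; the AR1 fit refines the full one),
the flattened two-way Gaussian mixture with unconstrained covariances
(via mclust, ICL selection), and k-means with silhouette-based selection
of $K$. Defaults are desk scale: 10 datasets of 769 genes with $K$
compared over 1–15, EM with 2 starts, tolerance `1e-7`, 200 iterations —
sizes chosen so a full run completes in a few minutes on one CPU while
leaving the qualitative contrasts clearly visible; all of them can be
raised through the function's arguments for a larger experiment. Child
seeds per dataset are derived deterministically from the master seed, so
a run is exactly reproducible.

The expected (and observed — see `scripts/acceptance.R`) pattern: the
three-way methods reach median ARI above 0.9 and select $K$ near 10,
while the two-way mixture, paying 55 covariance parameters per component,
underfits $K$ and loses ARI, and silhouette-selected k-means collapses to
very few clusters.

# Known limitations

* The unit-diagonal projection in the full-correlation M step can be
  rejected by the monotonicity guard near convergence; in that regime the
  correlation estimate stops updating at the guarded value. The effect on
  the solution is below the convergence tolerance in all tested settings.
* Likelihood surfaces of mixtures are multimodal; `n_starts` matters at
  large $K$, and the desk-scale defaults of the study trade some
  optimisation quality for speed.
* The AR1 refit can collapse at overfitted $K$ when the initialising
  full solution carries a near-empty component; `matmix_select()` then
  drops that $K$ with a warning rather than failing the sweep.
* Only an additive pseudo-count is offered for zeros; no Bayesian or
  robust imputation. Only the pivot basis is offered for ilr.
* Components are Gaussian; heavy-tailed or skewed component families are
  out of scope.
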