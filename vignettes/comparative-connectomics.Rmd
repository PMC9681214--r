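---
title: "Comparing connectomes across a taxonomy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing connectomes across a taxonomy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Structural connectomes reconstructed with a uniform parcellation (the same
number of nodes for every brain) can be compared across species even though
individual nodes do not correspond to one another: any *permutation-invariant*
summary of the network lives in a common frame of reference. `connectax`
implements two such summaries and the statistics built on top of them:

* **Spectral fingerprint.** The normalized graph Laplacian
  $L = I - D^{-1}A$ of the binarized connectome has all eigenvalues in
  $[0, 2]$; the sorted eigenvalue vector is a fingerprint of the topology.
  The *spectral distance* between two connectomes is one minus the cosine
  similarity of their eigenvalue vectors (optionally of Gaussian-smoothed
  eigenvalue densities, $\sigma = 0.015$ on a 2000-point grid over $[0,2)$).
* **Topological fingerprint.** A 22-entry vector: mean and SD of four local
  measures (degree, clustering, betweenness, closeness) in binary and
  weighted form, plus three global measures (characteristic path length,
  transitivity, assortativity) in binary and weighted form. The
  *topological distance* is one minus the cosine similarity of two feature
  vectors after per-feature z-scoring across all species being compared.

Given a species-by-species distance matrix and taxonomic order labels,
`intra_inter_compare()` contrasts same-order with different-order pairs with
two test/effect-size pairs: Welch's unequal-variance t-test with Cohen's
$d$ (classic pooled-SD denominator, positive when inter > intra) and the
Mann–Whitney U test with the common-language effect size
$\mathrm{CLES} = 100\,U/(n_1 n_2)$ (ties counted half).

A second family of analyses asks what is *conserved*: small-worldness
$S = \gamma/\lambda$ against degree-preserving rewired nulls, consensus
Louvain communities, rich-club organization with permutation significance,
and the relative proportions of edge classes (modular, hemispheric,
length-tercile, rich-club/feeder/peripheral).

# Conventions that matter

Formulas in the literature leave several degrees of freedom; these are the
package's fixed choices.

* **Weight-to-length map.** Weighted shortest paths run on edge lengths
  $1/w$. This is the stated example in the defining literature and the
  common convention for streamline-count weights.
* **Weighted clustering and transitivity** rescale weights to $[0,1]$ by
  the global maximum before taking cube roots (toolbox convention). This
  makes both measures invariant to global weight rescaling. Degrees in the
  denominators always come from the binarized matrix.
* **Closeness** is implemented exactly as the printed neighbourhood form:
  for node $i$, inverse shortest-path lengths between pairs of its
  neighbours, computed on the subgraph induced by the neighbourhood, and
  averaged over the $k_i(k_i-1)$ ordered pairs. This is structurally a
  *local-efficiency* quantity, not the conventional
  $1/\text{mean distance}$ closeness; the printed formula is deliberately
  not "corrected", because it is what the topological fingerprint used.
* **Betweenness** sums over ordered pairs and is normalized by
  $(n-1)(n-2)$.
* **Weighted assortativity** follows the printed per-link formula
  ($l^{-1}$ normalization with $w_{ij}$ weighting of strength products).
  This is not a bounded correlation coefficient; values slightly outside
  $[-1,1]$ can occur. Degree-regular graphs have no degree variance; the
  measure is undefined (NaN with a warning) and imputed as 0 inside
  feature vectors so cosine distances stay defined.
* **Characteristic path length** averages ordered pairs with finite
  distance; disconnected pairs are excluded and flagged. Synthetic and
  real connectomes are expected to be connected, so the flag is a
  data-quality signal rather than a routine code path.
* **Mean/SD of local measures** use the population SD (divide by $n$),
  matching the numerical stack the reference analysis was built on.
* **Feature standardization.** Whether feature vectors were z-scored
  before the cosine in the original analysis is not documented. Without
  standardization the cosine is dominated by large-magnitude features
  (mean degree, strength); with it every feature contributes comparably.
  Standardized is the default; `standardize = FALSE` gives the raw mode.
  Note z-scored vectors can be anti-parallel, so topological distances
  live in $[0,2]$ rather than $[0,1]$.
* **Laplacian eigendecomposition** is performed on the symmetric form
  $I - D^{-1/2} A D^{-1/2}$ (identical spectrum to $I - D^{-1}A$ by a
  similarity transform, numerically stable symmetric solver). The smoothing
  grid is the half-open $[0, 2)$ with step $0.001$ — exactly 2000 points;
  the smoothed density is renormalized to unit trapezoid area.

# The synthetic taxonomy

Real cross-species imaging data cannot ship with the package, so every
pipeline stage is exercised on a generated taxonomy whose statistical
structure matches what the analysis assumes
(`taxonomy_spec()` / `generate_dataset()`):

* **Order archetypes.** Each taxonomic order gets one bilateral stochastic
  block model: two equal hemispheres, order-specific module count
  (default $2, 3, \ldots, 7$ modules per hemisphere across 6 orders) and
  order-specific binary density (evenly spaced over 0.08–0.25, emulating
  the fact that density varies across orders). Within-module connection
  probability is 6 times the between-module probability, capped and
  re-balanced when a high density target saturates the modules.
  Inter-hemispheric wiring is a homotopic backbone (mirror-symmetric node
  pairs connected with probability 0.75) plus random crossings, budgeted
  at 12% of edges. Coordinates are mirrored Gaussian module clouds offset
  laterally; weights are log-normal with the log-mean decaying linearly in
  Euclidean distance (shorter edges are stronger).
* **Species** are degree-preserving rewirings of their order's archetype
  (default 5% of edges) plus multiplicative log-normal weight jitter
  (sdlog 0.10) and small coordinate jitter. Degree sequences are preserved
  exactly, so within-order variation is purely *local* rewiring — the
  mechanism the analysis attributes inter-species differences to.
* **Replicas** reuse the same perturbation with much smaller knobs (2%
  rewiring, 5% weight jitter), emulating high scan-rescan reliability.
* **Determinism.** One master seed; each connectome derives a substream
  seed by hashing (role, order, species, replica), so datasets are
  bitwise-reproducible and individual connectomes can be regenerated in
  isolation.

What a green test on this world does and does not establish: it shows the
pipeline separates planted architectural families and ranks feature
subsets as expected when within-order variation is local; it does not
certify tractography biases, allometric scaling, node-correspondence
effects, or any property of the real imaging data. Within-order
architectural homogeneity is idealized (all species of an order share one
degree sequence); real orders are messier.

# Numerical and procedural choices

* **Symmetry tolerance on input matrices**: asymmetry up to
  $10^{-8}\max|M|$ is silently symmetrized as $(M + M^\top)/2$; anything
  larger errors (tractography count matrices should be symmetric, larger
  asymmetry indicates corruption).
* **Replica control**: one scan per species is drawn uniformly, the full
  distance matrix computed (z-scoring within the iteration for the
  topological metric), and matrices are averaged element-wise across
  iterations (10,000 at study scale). Averaging matrices first — rather
  than averaging test statistics — follows the stated procedure of
  reporting average distances across iterations.
* **Density control**: per feature, a linear and an exponential model
  ($y = a e^{bx} + c$, Levenberg–Marquardt-style `nls` with log-linear
  initialization, linear fallback on non-convergence) are fitted against
  density; the better $R^2$ wins and the feature is replaced by residuals
  only when $R^2 > 0.1$.
* **Rewired nulls**: Maslov–Sneppen double-edge swaps, 10 swap attempts
  per edge, retrying (bounded) until the null is connected where
  connectivity is required. Small-world C and L are computed on binary
  graphs (the cited small-world literature is binary).
* **Consensus clustering**: 250 Louvain runs (weighted matrix by default,
  $\gamma = 1$), agreement matrix thresholded at the permutation-null
  expected agreement (the mean over runs of the probability that two
  random nodes co-assign given that run's community sizes), re-clustered
  until all runs agree, bounded at 50 iterations. The null-threshold
  choice (vs a fixed $\tau$) follows the agreement-matrix consensus
  literature; it is a design decision, as the original procedure cites
  the approach only by reference.
* **Rich club**: $\phi(k)$ over all $k$ with at least two surviving
  nodes; normalization by the mean $\phi$ of 1000 degree-preserving nulls;
  one-sided permutation $p$ with the $+1$ correction; selected level = the
  largest significant $\phi_{\mathrm{norm}} > 1$, ties toward larger $k$.
  Core membership at level $k$ uses the degree $\geq k$ convention that
  accompanies the $\phi(k)$ curve. The iterative-pruning k-core is also
  provided (`k_core_members()`), but is *not* used for club selection: a
  planted complete club of size $c$ has pruning-coreness at most
  $c - 1$ plus its peripheral degree, typically *below* the selected
  $k$, so the pruning rule can return an empty club exactly when the club
  is strongest.
* **$\phi_{\mathrm{norm}}$ sanity on homogeneous graphs**: the package's
  null-model check asserts *unbiasedness* — $\phi_{\mathrm{norm}}$
  averaged over independent random-graph draws is within 0.05 of 1 on the
  degree levels evaluable in every draw. Per-draw
  $|\phi_{\mathrm{norm}} - 1|$ is not small at the extreme tail (2–3
  surviving nodes make $\phi$ nearly Bernoulli), and no null-ensemble
  size fixes that; the tail is excluded by construction, not by tuning.
* **Edge-length classes**: Euclidean distance between node centroids as a
  percentage of the maximum inter-node distance; short $\leq 25\%$,
  medium $(25\%, 75\%]$, long $> 75\%$. The strict inequality for "long"
  resolves the overlapping printed boundaries at 75%.
* **MDS**: classical-scaling initialization followed by SMACOF stress
  majorization; Kruskal stress-1 is reported. Deterministic given the
  seed (randomness only pads rank-deficient classical solutions).

# Known limitations

* The quantitative reproduction of the published mammalian results
  requires the archived imaging-derived connectivity matrices, which are
  not redistributable inside the package; the pipeline (order filtering at
  5 species minimum, 10,000-iteration replica resampling, both distance
  metrics, both standardization modes) is in place and exercised on the
  synthetic taxonomy instead.
* Cosine-based distances are dissimilarities, not metrics (no triangle
  inequality); embedding and clustering of them are exploratory devices.
* Directed variants, weighted rich-club coefficients, and
  centrality measures beyond the printed set are out of scope.
* The generator does not simulate diffusion MRI, tractography biases, or
  allometric scaling; its defaults are a stated world, chosen once, not
  fitted to any dataset.
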