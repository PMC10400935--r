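---
title: "Transcriptional uncertainty landscapes from the two-state bursting model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional uncertainty landscapes from the two-state bursting model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstscape)
```

## The model

burstscape analyses single-cell expression data through the two-state
(telegraph) model of stochastic transcription. A gene's promoter switches
between an OFF and an ON state with rates $\theta_{on}$ (activation) and
$\theta_{off}$ (inactivation); mRNA is transcribed at rate $\theta_t$ only
while the promoter is ON and degrades at rate $\theta_d$. All rates are
normalized by mRNA degradation, so $\theta_d \equiv 1$ and the remaining
three rates are expressed per mRNA lifetime. Two derived quantities carry
the biological interpretation:

* **burst size** $S = \theta_t / \theta_{off}$, the mean number of
  transcripts made per ON episode, and
* **burst frequency** $F = \theta_{on}$, the rate of ON episodes.

At stationarity the mRNA copy number follows the Poisson–Beta mixture
$m \sim \mathrm{Poisson}(\theta_t\,p)$ with
$p \sim \mathrm{Beta}(\theta_{on}, \theta_{off})$. In the bursty regime
(slow switching, large $\theta_t$) this reproduces the heavy-tailed,
overdispersed count distributions typical of single-cell data; in the
fast-switching limit it approaches a Poisson.

A cell's likelihood is the joint probability of its counts — the product
over genes of the stationary probabilities under per-(gene, cluster)
parameters. Its negative logarithm, the cell's **NLL**, is the package's
measure of *transcriptional uncertainty*: cells in states with
high-entropy expression distributions are, on average, improbable under
any single parameterization, so high NLL marks heterogeneous, noisy
states, while cells in crisp, stable states have low NLL.

## The pipeline

1. **Preprocess** (`normalize_counts()`, `filter_cells()`,
   `filter_genes()`, `select_variable_genes()`): cap the matrix at the
   grid's `m_max` by one global scale factor (rounding half-up), filter
   cells/genes by expressed fractions, keep the most variable genes.
2. **Cluster** (`cluster_cells()`): greedy coordinate ascent on the total
   cell log-likelihood — alternately refit per-(gene, cluster) telegraph
   parameters by grid maximum likelihood and reassign each cell to its
   best cluster — repeated over seeded restarts to build a consensus
   matrix, finalized by k-medoids (PAM) on `1 - consensus/n_runs`. The
   number of clusters can be chosen by the eigengap of the consensus
   Laplacian (`eigengap_k()`).
3. **Lineage** (`infer_lineage()`): the distance between two clusters is
   the mean per-cell log-likelihood lost when they are refit as one;
   edges join clusters in ascending distance until the graph is connected
   (a spanning construction — edges whose endpoints are already connected
   through shorter edges are skipped). The root is the cluster with the
   smallest mean capture time; cluster pseudotime is hop depth below the
   root, rescaled along each branch so the root sits at 0 and every
   terminal fate at 1.
4. **Placement and uncertainty** (`place_cells()`): each cell is placed
   on an adjacent edge at the interpolation fraction $s$ maximizing
   $\sum_g \log[(1-s)P_{k_1,g}(m_g) + s\,P_{k_2,g}(m_g)]$ — a mixture of
   the endpoint clusters' count distributions, not of their parameters.
   The maximized value gives the cell's NLL (and its per-gene
   decomposition), and $s$ gives its pseudotime by linear interpolation.
5. **Summaries** (`nll_along_paths()`, `high_uncertainty_genes()`,
   `landscape_surface()`): moving-average NLL along each root-to-leaf
   path (window of 10% of the path's cells), per-cluster
   high-uncertainty gene calls (entries above the global mean + 3 SD in
   at least 30% of a cluster's cells), and the landscape: NLL over the
   first two principal components of the z-scored expression, fit on a
   regular 30×30 grid.
6. **Statistics** (`burst_uncertainty_table()`,
   `cellwise_velocity_and_nll()`, `lagged_cross_correlation()`): Pearson
   correlation of cluster-averaged gene NLL with burst size and
   frequency, using the score $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$
   degrees of freedom; and the lag analysis of cell-wise RNA-velocity
   magnitude (Euclidean norm over the gene panel) against mean NLL in
   equal-count pseudotime bins.

`run_pipeline()` chains all stages and writes every table as headered CSV
plus a manifest with the configuration, seed, and output checksums;
identical configuration reproduces identical files.

## Numerical choices

**PMF evaluation.** The Poisson–Beta mixture is computed by fixed-node
Gauss–Jacobi quadrature over the Beta density (512 nodes, Golub–Welsch on
the Jacobi recurrence), with the Poisson factors generated by the stable
upward recurrence from $e^{-\lambda}$. The test suite cross-validates
this against the confluent-hypergeometric series (Kummer-transformed so
all terms are positive), against $10^6$ exact mixture draws, and against
a Gillespie simulation of the full reaction network. Quadrature rather
than the series is the production path because the series' direct form
cancels catastrophically for large $\theta_t$.

**Fitting grid.** Maximum likelihood is searched over a log-spaced grid
with all PMFs precomputed and renormalized over `0..m_max` (so
likelihoods of different grid points are comparable on the truncated
support). The factory default is $\theta_{on}, \theta_{off} \in
[10^{-2}, 10^2]$ (20 points each), $\theta_t \in [0.1, 2\,m_{max}]$ (25
points), $m_{max} = 200$. The synthetic analyses in the tests and the
acceptance script use a desk-scale configuration — $\theta_{on} \in
[0.01, 10]$, $\theta_{off} \in [0.1, 100]$ (12 points each), $\theta_t$
with 18 points, $m_{max} = 150$ — for two reasons. First, runtime: the
consensus step refits every (gene, cluster) pair against the whole cache
at every iteration. Second, identifiability: for weakly expressed genes
the likelihood is nearly flat along ridges running into the
$\theta_{off} \to 0$ and $\theta_{on} \to \infty$ corners, and fits that
land there plant orders-of-magnitude outliers in $S = \theta_t /
\theta_{off}$ and $F = \theta_{on}$ which swamp raw-scale Pearson
correlations. Bounding the axes to the bursty regime that covers the
data-generating kinetics is a standard regularization of such grid
estimates. Ties in the grid argmax resolve to the smallest
$(\theta_t, \theta_{off}, \theta_{on})$ in lexicographic order, which
makes fits deterministic.

**Other conventions.** PAM (build+swap) is used for the k-medoids step —
it is deterministic, so no extra seeding is needed. PCA components fix
their sign by making the largest-magnitude gene loading positive. The
landscape solver is the classic gridfit formulation — bilinear
interpolation from grid nodes to data points with a second-difference
roughness penalty (default `smoothness = 1`, rescaled relative to the
data term), solved as a sparse regularized least-squares system;
constants and planes lie in the penalty null space and are reproduced
exactly. t-SNE is not bundled: `embed_2d()` takes PCA (the deterministic
default) or any user-supplied embedding function. Degenerate cases are
explicit: an all-equal consensus warns and splits arbitrarily but
deterministically; an uninformative eigengap returns K = 2 with a
warning; a singular landscape system retries with increased smoothness.

## The synthetic lineage generator

`lineage_scenario()` / `generate_lineage_data()` produce
lineage-structured counts with full ground truth so every pipeline stage
can be validated offline. The design mimics the features of real
differentiation data that the analysis actually uses:

* **Cluster programs.** Every gene has an *active* kinetic state
  ($\theta_{on} \sim 10^{U(-0.3, 0.5)}$, $\theta_{off} \sim
  10^{U(-0.5, 0.5)}$, $\theta_t \sim 10^{U(1, 1.5)}$) and a *silent* one
  (activation 10–16× slower, transcription 4–6× weaker — still visibly
  bursty when it fires, as real "off" genes are). Roughly half the genes
  start active at the root.
* **Tree structure.** Each lineage edge toggles a balanced marker block
  (default 15% of genes, half switched on and half off) drawn without
  reuse across edges, and lets a further 25% of active transcription
  rates drift by a mild random factor. Balanced toggling keeps the size
  of the active program — hence the baseline NLL — flat along the
  lineage; disjoint blocks make cluster distances add up along paths
  instead of partially cancelling, so the likelihood-based distance
  behaves like a tree metric and the spanning construction recovers the
  planted topology.
* **Transition states.** Designated clusters get burst inflation: a
  subset of genes (default 20%) has burst size multiplied by `inflation`
  (default 5, split as $\theta_t \times \sqrt{f}$, $\theta_{off} /
  \sqrt{f}$) and burst frequency by $\sqrt{f}$ ($\theta_{on}$). Two of
  the weakest-expressed active genes are inflated — giving the velocity
  proxy a mean-expression signature — and the rest are silent genes,
  whose de-repression emulates the exploratory transcription of
  transition states: it adds entropy (uncertainty) at almost no shift in
  mean expression, because the NLL gain depends on the variance ratio
  while the distortion of cluster distances scales with absolute
  expression.
* **Velocity proxy.** For a cell at lineage depth $d$, the per-gene
  velocity is the absolute difference between the mean expression of the
  cluster(s) at depth $d + \Delta$ (default $\Delta = 1$) and its own
  cluster's mean, plus seeded Gaussian noise (SD = 5% of the largest
  entry). Its magnitude therefore rises one cluster before the
  inflation-driven NLL rise — a controllable stand-in for the empirical
  observation that RNA velocity leads uncertainty. It is a
  forward-difference construct, not a spliced/unspliced kinetic model.
* **Pseudotime truth.** Planted pseudotime is cluster depth scaled to
  [0, 1] plus Gaussian jitter (SD 0.02) — enough to define an order
  within clusters without making it recoverable exactly.

Presets `linear-4`, `linear-6`, `bifurcation-5` (one branch point) and
`two-bifurcation-7` (two branch points) fix 100 cells per cluster and
50–60 genes — the scale of the plate-based scRT-qPCR studies this class
of analysis was developed on. What the generator deliberately omits:
dropout/zero-inflation beyond the model's own zeros, UMI saturation, Ct
quantization, library-size variation, doublets, and cell-cycle
structure. Passing tests therefore demonstrate the pipeline's internal
consistency and its behaviour under the model's own assumptions, not
robustness to platform-specific artefacts.

## Validated properties

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch at a caller-supplied seed) checks, on the preset
scenarios at their standard conditions:

* stationary PMFs within total-variation 0.005 of $10^6$ exact draws and
  0.01 of a Gillespie simulation; exact Poisson and zero-transcription
  limits;
* burst-size rank correlation ≥ 0.9 between grid-MLE fits and truth over
  50 genes × 500 cells, and exact agreement of the vectorized grid
  search with a naive exhaustive scan;
* consensus clustering ARI ≥ 0.9 against planted labels with the true K;
  monotone greedy objective; eigengap recovery of planted block counts;
* exact recovery of the planted linear, bifurcating and doubly
  bifurcating topologies; near-zero distance between identical-parameter
  clusters; pseudotime Spearman ≥ 0.8 against the planted order;
* the rise-then-fall signature: the moving-average NLL peaks within
  ±0.15 pseudotime of the planted transition on every root-to-leaf path,
  the transition cluster's mean NLL exceeds the terminal clusters', and
  the double-bifurcation scenario shows two distinct peaks;
* positive Pearson correlation (p ≤ 0.01, via the $t$ score above) of
  cluster-averaged NLL with both burst size and burst frequency;
* a strictly positive lead of velocity magnitude over NLL in the lag
  analysis (the planted one-cluster lead is recovered as +4 of 20
  equal-count bins, i.e. one cluster);
* byte-identical outputs across repeated pipeline runs with the same
  master seed.

Test problem sizes (12×12×18 grid, 8 consensus runs, the preset cell
numbers) are the package's desk-scale choices; the defaults in
`default_config()` are larger.

## Known limitations

Grid maximum likelihood quantizes parameters to the grid; burst
statistics inherit that resolution, and for genes in the
weak-identifiability regimes discussed above the individual $S, F$
estimates are noisy even though rank structure and correlations are
stable. The lineage graph is a cluster-level spanning construction: it
cannot represent cycles or convergent fates, and edge recovery degrades
when a transition state's expression shift rivals a full lineage step.
Cell placement considers only edges adjacent to the assigned cluster, so
misclustered cells get locally-best but globally wrong pseudotimes.
Numeric parity with other implementations of this analysis family is not
guaranteed: the stationary-PMF evaluation scheme and the fitting grid
are reconstructions chosen here, not published constants.
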