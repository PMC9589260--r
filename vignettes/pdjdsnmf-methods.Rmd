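---
title: "Methods: prior-driven joint deep semi-NMF for multi-omics modules"
author: "pdjdsnmf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prior-driven joint deep semi-NMF for multi-omics modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdjdsnmf)
```

## The model

Given three expression matrices $X_i \in \mathbb{R}^{n \times p_i}$
(conventionally mRNA, lncRNA and miRNA) over the same $n$ samples, the
package factorizes them jointly as

$$X_i \approx U H_i^0,$$

with one shared sample-latent matrix $U \in \mathbb{R}^{n \times k_0}$
(unconstrained sign) and per-omics first-layer coefficients
$H_i^0 \in (0,1)^{k_0 \times p_i}$.  The coefficients are not free
parameters: they are the top of a sigmoid-activated hierarchy

$$H_i^{m-1} = s(Z_i^m H_i^m), \qquad m = 1,\dots,N, \qquad
  s(x) = \frac{1}{1 + e^{-x}},$$

where the junction matrices $Z_i^m \in \mathbb{R}^{k_{m-1}\times k_m}$ and
the deepest layer $H_i^N \in \mathbb{R}^{k_N \times p_i}$ are unconstrained.
The sigmoid makes every derived layer automatically nonnegative (in fact in
$(0,1)$), so this is a semi-NMF: only the coefficient side is sign
constrained.  The depth gives the factorization a nonlinear manifold to
work with; a single linear nonnegative layer (classical joint NMF) is kept
as the `"jnmf"` ablation, and the hierarchy without priors as `"jdsnmf"`.

The fitted objective is

$$\sum_{i=1}^{3} \lVert X_i - U H_i^0 \rVert_F^2
  \;+\; \lambda_1 \sum_{S} \lVert S \rVert_F^2
  \;+\; \lambda_2 \,\mathrm{Tr}\!\left(H^0_{\mathrm{ppi}} M\, H^{0\top}_{\mathrm{ppi}}\right)
  \;+\; \lambda_3 \sum_{i=1}^{3} \mathrm{Tr}\!\left(H_i^0 B_i H_i^{0\top}\right),$$

where $S$ ranges over $U$, all $Z_i^m$ and all $H_i^N$ (ridge on every free
parameter), $B_i = D_i - L_i$ is the graph Laplacian of a per-omics feature
connectivity matrix $L_i$, and $M$ encodes the protein--protein-interaction
(PPI) prior on the omics that carries it.  Because
$\mathrm{Tr}(H B H^\top) = \tfrac12 \sum_{p,q} L_{pq}\lVert h_p - h_q\rVert^2$
over feature columns $h$, the $\lambda_3$ term pulls strongly co-expressed
features toward similar factor loadings — a smoothing that resists additive
noise — and the $\lambda_2$ term does the same for interacting proteins.

Three modelling choices here were genuinely open and are worth recording:

* **Orientation and form of the PPI term.**  A literal trace of the raw
  adjacency over a $k_0 \times p$ coefficient matrix is not dimensionally
  conformable in the orientation we store, and its sign is ambiguous
  (penalize vs. reward co-activation).  The default (`ppi_mode =
  "laplacian"`) uses the Laplacian of the PPI adjacency, for which the
  term is a nonnegative quadratic form that *rewards similar loadings on
  interacting proteins* — the stated purpose of adding the prior.  A
  `"literal"` mode (raw adjacency as $M$) is kept for fidelity
  experiments; it is not positive semidefinite and can reward or punish
  co-activation depending on sign structure.
* **Quadratic penalty.**  The pairwise form of the connectivity penalty is
  implemented as the standard squared difference
  $\tfrac12\sum L_{pq}\lVert h_p-h_q\rVert^2$, the unique form consistent
  with its trace expression $\mathrm{Tr}(H^\top B H)$.
* **Which omics carries the prior.**  An explicit `ppi_omics` argument;
  by default the omics whose feature set matches the prior's node set.

## Feature connectivity graphs

The source publications in this model family never specify how the
connectivity matrices $L_i$ are built.  The package constructs them from
the data: `build_feature_graph()` connects features with absolute Pearson
correlation $\lvert r\rvert \ge \tau$ (default $\tau = 0.8$; binary edges
by default, `weighted = TRUE` keeps $\lvert r \rvert$), or by OR-symmetrized
$k$-nearest neighbours for dense panels.  Zero-variance features get no
edges rather than propagating `NaN`.  Laplacians are validated to have zero
row sums and to be positive semidefinite.

## Optimization

The sigmoid chain rules out classical multiplicative NMF updates, so the
model is fit by full-batch first-order descent with adaptive moment
estimation (default step size $10^{-2}$) on $U$, all $Z_i^m$ and all
$H_i^N$; gradients are exact analytic backpropagation through the chain
($\mathrm{d}s = s(1-s)$), verified against central finite differences in
the test suite.  Two safeguards make the trace trustworthy:

* **Monotone acceptance.**  A step is accepted only if it does not
  increase the objective (relative slack $10^{-12}$); otherwise the step
  size is halved and retried.  The objective trace is therefore
  non-increasing by construction.
* **Moment restart.**  When the adaptive direction stops descending, the
  moments are reset and the iteration falls back to backtracking plain
  gradient descent; only if that also fails is the point declared
  stationary.

Iteration stops at a relative objective change below `tol` (default
$10^{-5}$; the convergence studies in the tests use $10^{-8}$–$10^{-9}$) or
at `max_iter` (default 2000).  A divergent configuration (non-finite
objective) raises an error suggesting a smaller learning rate rather than
returning garbage.

Expression matrices are min–max scaled per feature to $[0,1]$ by default
(`scale = TRUE`), since $H^0 \in (0,1)$ and $U$ absorbs scale; synthetic
data generated by the package's own model class are already on that scale,
so the bundled studies fit with `scale = FALSE`.

## Initialization

Initialization follows a truncated SVD of the column-concatenated data
$[X_1\,X_2\,X_3]$.  Two refinements matter:

* **Simple-structure rotation.**  The residual and both quadratic
  penalties are invariant under convex mixing of the factors (same-module
  feature columns are near-identical, so the Laplacian term cannot
  distinguish a rotation), which means the optimizer essentially keeps the
  basis it starts from.  Raw singular vectors are an arbitrary rotation of
  any parts-based structure; the right factor is therefore varimax-rotated
  (deterministically, preserving the rank-$k_0$ reconstruction exactly)
  before being squashed into $(\varepsilon, 1-\varepsilon)$,
  $\varepsilon = 10^{-4}$.  Without this rotation, planted-module recovery
  on synthetic data collapses (best-match F1 $\approx 0.07$ instead of
  $\approx 0.9$) even though the reconstruction correlation is equally
  good — a direct illustration of the rotational ambiguity.
* **Chain descent and alternating refit.**  Deeper layers are obtained by
  recursively logit-transforming the current layer and truncating its SVD
  at the next width, with a few alternating least-squares rounds in logit
  space per level and a bottom-up least-squares refit of each junction.
  Finally $U$ is refit by least squares against the derived $H^0$, and up
  to four alternating passes (new target $\mathrm{clamp}(U^{+}X)$,
  re-decompose, refit $U$) are tried, keeping the best pass by residual —
  the alternation is not monotone, so the best intermediate is retained.
  On noiseless rank-$k_0$ data this initialization alone reaches mean
  reconstruction correlation above 0.9 before any training.

All of this is deterministic; the `seed` is recorded with the model and
governs the only stochastic elements elsewhere (data generation, sampling
in tests).

## Module extraction

Each of the $k_0$ factors defines one co-expression module.  For factor
$r$ and omics $i$ the row $H_i^0[r,\cdot]$ is standardized across features,
and feature $j$ joins the module when
$z_j = (H_i^0[r,j] - \bar h)/\mathrm{sd}(h) \ge$ `zscore_threshold`.  The
threshold is not fixed by the model family; the default 1.96 (the 5%
two-sided normal tail) follows common practice in this lineage and is
configurable.  One-sided thresholding is the default — a module is the set
of features loading *heavily* on a factor — with `two_sided = TRUE`
available to capture anti-correlated members.  z-scores are computed per
factor row across features (not per feature across factors) because
membership asks which features load on a given factor; the z-score is also
invariant to the row rescaling that the factorization leaves free.  A
module's reconstruction correlation is the Pearson correlation between the
data restricted to its member features and the corresponding columns of
$U H^0$, flattened and pooled across the three omics; per-omics values are
available from the same machinery.

## Model selection

`lambda_grid_search()` fits every $(\lambda_1,\lambda_2,\lambda_3)$
combination from a penalty grid (the default three-point grid
$\{0.001, 0.01, 0.1\}$ gives $27$ combinations, enumerated with $\lambda_3$
fastest) and `dims_sweep()` fits each candidate dimension profile, both
scored by per-omics and mean reconstruction Pearson correlation.  All fits
share one seed and hence one initialization, so score differences reflect
the penalties or dimensions, not initialization noise (the alternative —
averaging over seeds — is available by calling the functions repeatedly).
The sweep reports the mean and, because the convention is ambiguous in
published tables, both the population ($\div m$) and sample ($\div (m-1)$)
standard deviation across the per-omics correlations; selection maximizes
the mean with ties broken by the smallest population deviation.  The
default dimension profile decreases with depth (e.g. $30 > 25 > 20 > 15$
at full scale, $10 > 8 > 6 > 4$ at desk scale), consistent with the
published sweeps in this model family; an increasing profile would make
the truncated-SVD chain ill-posed.

## The synthetic generator

`generate_synthetic()` emulates exactly the data structure the model
assumes — it is the model class, not a caricature of real data:

* planted membership: `n_modules` $= k_0$ modules with `module_size`
  members per omics (disjoint when capacity allows);
* a target first layer with member logits $+a$ and background $-a$
  (default amplitude $a = 3$, i.e. loadings near 0.95 vs 0.05, with mild
  jitter), *imposed on the derived layer*: the chain parameters
  $Z, H^N$ are obtained by decomposing and then descent-refining the chain
  against the target, so the planted model is a genuine member of the
  model class rather than painted on post hoc;
* $U$ with i.i.d. standard normal entries and
  $X_i = U H_i^0 + \varepsilon$, with noise variance set by the
  signal-to-noise ratio `snr` (variance ratio, linear scale; default 10);
* a PPI prior sampled blockwise over the first omics (edge probability
  0.5 within planted modules, 0.01 between — a strong but not clean
  prior).

Defaults ($n = 100$, $p = (300, 120, 30)$, dims $(10, 8, 6, 4)$, module
sizes $(20, 8, 3)$) mimic the mRNA $\gg$ lncRNA $\gg$ miRNA ordering of
bulk heart-tissue panels at desk scale; the published full-scale analyses
in this family use $p \approx (14914, 3134, 30)$ with $k_0 = 30$, which
the same code handles but which is deliberately not the test-suite scale.
What the generator does **not** emulate: heavy-tailed count distributions,
batch effects, library-size artefacts, or differential-expression
prefiltering.  Passing the bundled studies therefore shows the estimator
recovers its own model class under Gaussian noise — a necessary check, not
evidence about any particular tissue dataset.

Recovered modules are matched to planted ones by maximizing summed member-set
F1 under an optimal one-to-one (Hungarian) assignment, and
`score_recovery()` reports the mean matched F1.

## Problem sizes and numerical choices in the bundled studies

The package's own studies (test suite and `scripts/acceptance.R`) use:
noiseless recovery at $n=40$, $p=(60,40,20)$, dims $(8,6,4)$ (mean
reconstruction correlation $\ge 0.99$); module recovery at the generator
defaults over five seeds (mean best-match F1 $\ge 0.8$, observed
$\approx 0.97$–$1.0$); descent and determinism checks at small sizes; and
the ablation comparison at $n=60$, $p=(120,60,20)$, snr $=2$ with a fixed
budget of 300 iterations.  The fixed budget is deliberate: at full
convergence the penalized model cannot systematically beat its unpenalized
ablation on *in-sample* reconstruction (the penalties only restrict the
same model class), whereas in the practical fast-convergence regime the
prior terms guide the optimizer to better basins under noise — which is
the regime the comparison is about.

Degenerate inputs are rejected at validation rather than patched: an omics
with $p_i < k_0$, $k_0 > n$, misaligned sample orders, asymmetric
adjacencies beyond $10^{-9}$, non-finite cells in expression files.
Constant factor rows yield no module members (logged), constant features
scale to 0.5, and empty modules report a flagged missing correlation.

## Known limitations

* Factor recovery relies on the varimax-rotated initialization staying in
  the right basin; extremely low signal-to-noise or heavily overlapping
  planted modules can still end in mixed factors.
* The Laplacian graphs are built from the same data being fit; at very
  small $n$ the correlation graph is noisy and the $\lambda_3$ term can
  smooth across spurious edges.
* In-sample reconstruction correlation — the selection criterion of this
  model family — rises with fitted noise; it is a reconstruction metric,
  not an out-of-sample validation.
* The optimizer is full-batch; the intended regime is hundreds of samples
  and up to a few tens of thousands of features, not single-cell-scale
  matrices.
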