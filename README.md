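# pdjdsnmf

Joint decomposition of multi-omics expression data into shared factors and
prior-regularized nonlinear coefficient hierarchies, with co-expression
module extraction.

## The problem

Bulk transcriptomic studies of complex disease increasingly measure several
RNA species — mRNA, lncRNA and miRNA — on the same samples.  The molecules
regulate one another, so the interesting structure (which features move
together, and which samples drive them) lives *across* the matrices, not in
any one of them.  This package is for analysts who want to integrate three
such matrices into a small set of cross-omics **co-expression modules**,
optionally steering the factorization with protein–protein-interaction
(PPI) prior knowledge and noise-resisting feature-graph smoothing.

## The model

Given $X_i \in \mathbb{R}^{n \times p_i}$ ($i = 1,2,3$) over shared
samples, the package fits a joint deep semi-nonnegative factorization

$$X_i \approx U H_i^0, \qquad
  H_i^{m-1} = s\!\left(Z_i^m H_i^m\right),\quad m = 1,\dots,N,$$

with a shared sample-latent matrix $U \in \mathbb{R}^{n\times k_0}$
(unconstrained sign), per-omics junction matrices $Z_i^m$, a deepest
feature-latent layer $H_i^N$, and the logistic sigmoid $s$ keeping every
derived coefficient layer in $(0,1)$.  The objective adds three penalties,

$$\textstyle\sum_i \lVert X_i - U H_i^0\rVert_F^2
  + \lambda_1 \sum_S \lVert S\rVert_F^2
  + \lambda_2\,\mathrm{Tr}\!\left(H^0_{\mathrm{ppi}} M H^{0\top}_{\mathrm{ppi}}\right)
  + \lambda_3 \sum_i \mathrm{Tr}\!\left(H_i^0 B_i H_i^{0\top}\right),$$

where $M$ is (by default) the Laplacian of the binary PPI adjacency and
$B_i$ the Laplacian of a per-omics feature-connectivity graph — both terms
pull interacting / co-expressed features toward similar factor loadings.
Fitting is full-batch adaptive gradient descent with a monotone safeguard
(the objective trace never increases), initialized from a varimax-rotated
truncated SVD.  Each of the $k_0$ factors then yields one module: the
features whose per-factor coefficient z-score exceeds a threshold
(default 1.96), scored by member-restricted reconstruction correlation.

Also included: penalty-grid and layer-dimension model selection scored by
reconstruction Pearson correlation, ablation variants (`jdsnmf`: no
priors; `jnmf`: single linear nonnegative layer), a planted-module
synthetic generator with module-consistent PPI priors, recovery scoring by
optimal F1 matching, TSV/JSON checkpoints, and a CLI.

See `vignettes/pdjdsnmf-methods.Rmd` for the modelling and numerical
choices in full.

## Worked example

Generate a planted-module instance at the default desk scale
($n = 100$ samples; $300$ mRNA, $120$ lncRNA, $30$ miRNA features;
$k_0 = 10$ planted modules; signal-to-noise ratio 10), fit the full model,
and extract modules:

```r
library(pdjdsnmf)

sim    <- generate_synthetic(synthetic_spec(seed = 1))
graphs <- lapply(sim$X, build_feature_graph, tau = 0.8)
fit    <- fit_pdjdsnmf(sim$X, dims = c(10, 8, 6, 4), P = sim$P,
                       graphs = graphs, seed = 1, scale = FALSE,
                       max_iter = 2500, tol = 1e-8, learning_rate = 5e-2)
print(fit)
#> pdjdsnmf_fit (pdjdsnmf): 137 iterations (converged), objective 25336.4
#>   reconstruction correlations: mRNA=0.8176  lncRNA=0.8130  miRNA=0.8447  mean=0.8251

modules <- score_modules(extract_modules(fit, zscore_threshold = 1.96),
                         fit, sim$X)
summ <- module_summary(modules)
head(summ[order(summ$rank), ], 3)
#>   module n_mRNA n_lncRNA n_miRNA correlation rank
#> 2      2     20        3       1   0.9189679    1
#> 6      6     19        8       2   0.8919863    2
#> 1      1     20        8       3   0.8826006    3
attr(summ, "mean_members")
#>   mRNA lncRNA  miRNA
#>   19.2    8.0    2.5

score_recovery(modules, sim$truth$modules)$mean_best_f1
#> [1] 0.8493881
```

Reading the output: the fit reconstructs each (noisy) matrix with Pearson
correlation ≈ 0.82–0.84 — close to the noise ceiling
$\sqrt{\mathrm{snr}/(1+\mathrm{snr})} \approx 0.95$ for in-sample
correlation at this noise level once regularization is on.  Ten modules
are returned (one per factor); the best-reconstructed module correlates at
0.92 with the data restricted to its members, and the recovered member
sets match the planted truth with mean best-match F1 ≈ 0.85.

The same pipeline is available from the shell:

```sh
inst/cli/pdjdsnmf simulate --out sim --seed 0
inst/cli/pdjdsnmf fit --mrna sim/mRNA.tsv --lncrna sim/lncRNA.tsv \
    --mirna sim/miRNA.tsv --ppi sim/ppi_edges.tsv --dims 10,8,6,4 \
    --no-scale --out fit0
inst/cli/pdjdsnmf modules --model fit0 --out mods
```

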