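# mthess

Bayesian hierarchical sparse regression for mapping associations between a
large panel of predictors (SNPs) and many responses (gene expression)
measured in several tissues, cell types or conditions — with particular
focus on detecting regulatory **hotspots**, markers associated with many
responses at once.

## Who this is for

eQTL analyses that measure the same transcripts in multiple tissues usually
either intersect per-tissue hit lists (conservative, fragile under
signal-to-noise imbalance) or test each SNP–transcript pair separately
(blind to linkage disequilibrium and to hotspot structure). `mthess` fits
the whole problem jointly: a fully multivariate model search over markers
for every response, a matrix-variate model of the between-tissue residual
correlation, and a hierarchical selection prior that pools evidence across
responses.

## The model

For each response $k$, the $n \times r$ stack $Y_k$ (individuals ×
conditions) follows

$$Y_k = A_k + X_{\gamma_k} B_{\gamma_k} + E_k,\qquad
E_k \sim \mathcal{N}(I_n, \Sigma_k),$$

with a binary selection row $\gamma_k$ shared by all conditions, a g-prior
on the effects, an inverse-Wishart prior on $\Sigma_k$ (degrees $d = 3$,
scale $h_k I_r$), and a flat intercept prior. The intercept, effects and
residual covariance integrate out in closed form:

$$\log p(Y_k \mid X,\gamma_k,g) = \text{const}
 - \tfrac{r|\gamma_k|}{2}\log(1+g)
 - \tfrac{d+n+r-2}{2}\log\Big|h_k I_r + \tfrac{1}{1+g}Y_k'Y_k +
   \tfrac{g}{1+g}R(\gamma_k)\Big|$$

where $R(\gamma_k)$ is the residual cross-product of $Y_k$ on the selected
markers. Selection probabilities decompose as
$P(\gamma_{kj}{=}1) = \omega_k\,\rho_j$: the Beta-distributed $\omega_k$
carries per-response sparsity, the Gamma(1.2, 1.2)-distributed $\rho_j$
carries marker $j$'s hotspot propensity, and
$g \sim \text{InvGamma}(q/2 + q - 1,\, nq/2)$ adapts the Zellner–Siow
shrinkage prior to $q$ responses. Posterior sampling uses an Evolutionary
Monte Carlo scheme — tempered parallel chains with local add/delete/swap
moves (including LD-informed swaps), per-response crossover between
chains, temperature exchange, and random-walk updates of
$(\omega, \rho, g)$ — implemented in C++.

Associations are summarized by marginal posterior probabilities of
inclusion (MPPI), thresholded either directly or through the Bayesian FDR
$\mathrm{bFDR}(c) = \sum(1-\pi)\mathbb{1}[\pi>c] / \sum\mathbb{1}[\pi>c]$;
hotspots are per-marker counts of called responses. A leave-one-out
posterior-predictive check scores model adequacy, and a simulation module
plus MANOVA / single-tissue baselines form a complete evaluation harness.

## Worked example

Simulate a small multi-tissue dataset with two planted hotspots, run the
sampler, and call associations at a 5% Bayesian FDR:

```r
library(mthess)

cfg <- sim_config(n = 29, p = 120, q = 30, r = 3, n_chrom = 10,
                  sigma_total = rep(0.1, 3), sigma_shared = 0,
                  pattern = "cis_trans", seed = 7)
dat <- simulate_dataset(cfg)

hp <- default_hyperparams(dat$X, dat$Y, e_gamma = 1, v_gamma = 4)
tr  <- run_sampler(dat$X, dat$Y, hp,
                   sampler_config(n_sweeps = 6000, burn_in = 2000, seed = 1),
                   ladder_config(n_chains = 3))
mppi <- compute_mppi(tr)

th <- threshold_for_bfdr(mppi, 0.05)
calls <- association_calls(mppi, th$threshold)
head(hotspot_table(calls), 4)
```

```
#> mthess_trace: 4000 recorded sweeps, q = 30 responses, p = 120 markers
#>   posterior mean g = 30.907
#> threshold = 0.538, bFDR = 0.042, 29 pairs called
#>     marker_id n_responses
#> M64       M64           6
#> M51       M51           5
#> M36       M36           4
#> M3         M3           2
```

The planted pattern puts hotspots of sizes (2, 2, 4, 4, 6, 6) at markers
M1, M11, M24, M36, M51 and M64: the two six-response hotspots (M64, M51)
and one four-response hotspot (M36) are recovered essentially in full at
this threshold, with the smaller blocks partially recovered (the call at
M3 tags an LD partner of the M1 hotspot). The ground truth is in
`dat$truth` and the evaluation helpers compare against it:

```r
roc <- roc_points(score_matrix(mppi), dat$truth)
attr(roc, "auc")
#> [1] 0.999
```

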