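# hamball

Hamming ball sampling for Bayesian inference in high-dimensional discrete
latent spaces.

## The problem

Posteriors over large discrete latent objects — a binary inclusion vector
over thousands of regression covariates, or a binary genotype matrix
describing tumor subclones — cannot be enumerated, and conditional
(Gibbs) samplers that change one or two entries at a time get trapped when
entries are strongly correlated: two duplicated covariates that explain
the response equally well, or two subclonal architectures consistent with
the same variant allele frequencies, are separated by low-probability
valleys that small moves cannot cross.

`hamball` implements an auxiliary-variable MCMC scheme that slices the
state space into *Hamming balls*. An auxiliary copy **U** of the latent
state **X** is drawn uniformly from the neighbourhood

    H_m(X) = { U : d(u_i, x_i) <= m  for every block i },

where `d` is the Hamming distance on blocks (matrix columns, or random
chunks of size `K`). Conditional on **U**, the latent state lives in the
tractable slice `H_m(U)` — a ball of `M = sum_{j<=m} (S-1)^j C(K, j)`
states per block instead of `S^K` — inside which exact summation and
sampling are feasible. The slice moves with **U**, making the chain
ergodic, and one iteration can change up to `2mP` entries jointly. Setting
`m = K` recovers exact block Gibbs / fully marginalised sampling; `m < K`
trades per-iteration reach against an `O(MP)` cost the user controls.

The package provides:

* the ball combinatorics (`hamming_distance`, `ball_volume`,
  `enumerate_ball`, `sample_ball`, `in_ball`), including the
  distance-weighted `exp(-lambda d)` variant;
* generic kernels against a plug-in model contract (`hb_model`):
  `block_hb_sweep`, `block_gibbs_sweep`, `hb_gibbs_iteration`,
  `hb_marginal_mh_iteration`, `msss_iteration` (Metropolized Shotgun
  Stochastic Search comparator), `random_radius_iteration`, and a
  `run_chain` driver;
* three worked models: a toy spike regression with known coefficients
  (`toy_model`, `run_toy_experiment`), sparse variable selection under a
  Zellner g-prior with all continuous parameters marginalised analytically
  (`regression_block_hb`, compiled sweep), and binomial-mixture tumor
  subclonal deconvolution from variant allele frequencies, including a
  multi-sample extension (`deconv_hb`);
* seeded synthetic-data generators for each study design (`gen_toy`,
  `gen_regression`, `gen_tumor`, `gen_multisample_tumor`);
* diagnostics: integrated autocorrelation time and effective sample size
  (`iat`, `ess`), mode-switch counts (`mode_switches`), trace-density mode
  locations (`trace_modes`), and model-fit residual matrices
  (`residual_matrix`).

## Worked example: is the tumor linear or branched?

Nine variants sequenced at depth 800 have variant allele frequencies near
0.5, 0.3 and 0.15 in groups of three. A *linear* phylogeny (nested
genotypes, largest subclone weight 0.4) and a *branched* phylogeny
(largest weight 0.6) explain these frequencies equally well. A sampler
that reports only one of them is misleading; the Hamming ball sampler
visits both.

```r
library(hamball)

tum <- gen_tumor()          # reference counts: r = 405, 397, ..., 123
fit <- deconv_hb(tum$counts, deconv_hyper(K = 8, m = 4),
                 iterations = 20000, burn_in = 10000, seed = 1)
fit
#> Hamming ball deconvolution fit (K = 8 , m = 4 )
#>   variants x samples: 9 x 1
#>   recorded iterations: 20000
#>   acceptance rate: 0.176 (tuned sigma_v2 = 0.125 )

round(fit$phi_mean[, 1], 3)
#> [1] 0.499 0.499 0.498 0.306 0.309 0.310 0.156 0.154 0.156

trace_modes(fit$max_theta[, 1], min_mass = 0.05)
#>    location   mass    lower    upper
#> 1 0.3901157 0.6967     -Inf 0.482584
#> 2 0.5963911 0.3033 0.482584      Inf
```

The fitted allele frequencies recover the observed `r/d` to a few
thousandths (the residual matrix `residual_matrix(fit$r, fit$d,
fit$phi_mean)` is below 0.008 everywhere), and the trace of the largest
mixture weight is bimodal: roughly 70% of posterior mass sits at
max&nbsp;θ ≈ 0.39 — the linear architecture — and 30% at ≈ 0.60, the
branched one. A block Gibbs sampler on the same model typically reports
only one of these modes.

The regression counterpart behaves the same way: on a 100 × 1200 design
whose second half duplicates the first, the block Hamming ball sampler
(`regression_block_hb` with `K = 10`, `m = 1`) gives the two duplicated
relevant covariates posterior inclusion probabilities near 0.5 each,
switching between them throughout the run, while small-block Gibbs
samplers stick with whichever replica they find first.

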