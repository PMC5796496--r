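---
title: "Hamming ball sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hamming ball sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hamball)
```

## The problem

Many latent-structure models place a posterior over a high-dimensional
discrete object **X** — a binary inclusion vector over thousands of
covariates, or a binary genotype matrix over subclones and variants — whose
state space is far too large to enumerate. Single-site or small-block Gibbs
sampling is tractable but moves through that space one or two entries at a
time; when entries are strongly correlated (two duplicated covariates that
explain the data equally well, two subclonal architectures consistent with
the same allele frequencies), the chain gets trapped at one mode and the
posterior is misrepresented.

## The auxiliary-variable construction

`hamball` implements a slice-sampling idea adapted to discrete spaces. The
model is augmented with an auxiliary copy **U** of the latent state, drawn
uniformly from the *Hamming ball* around **X**: the set of states whose
per-block Hamming distance from **X** is at most a radius $m$,

$$H_m(\mathbf X) = \{\mathbf U : d(\mathbf u_i, \mathbf x_i) \le m,\;
i = 1, \dots, P\},$$

where the blocks are matrix columns or random chunks of size $K$. Because
the ball volume $M = \sum_{j=0}^{m} (S-1)^j \binom{K}{j}$ does not depend on
the centre, $p(\mathbf U \mid \mathbf X)$ is uniform with a closed-form
normaliser, and Gibbs sampling on the augmented model leaves the original
posterior invariant. Conditional on **U**, the latent state is confined to
the tractable slice $H_m(\mathbf U)$, inside which exhaustive summation is
feasible; the slice itself moves randomly with **U**, which restores
ergodicity. One iteration can change up to $2mP$ entries of **X** — a joint
move no small-block conditional sampler can make.

Two regimes connect the scheme to familiar samplers:

* $m = K$ makes the ball the whole block space: the kernels reduce to exact
  block Gibbs (or fully marginalised) sampling, at $O(S^K P)$ cost.
* $m < K$ trades per-iteration reach against cost $O(MP)$: radius 1 on a
  block of 10 binary entries sums 11 terms instead of 1024.

## Kernels

All kernels share the ball primitives in `ball_geometry` (distances,
volumes, deterministic enumeration, and sampling within a ball that never
materialises it: a distance class is drawn with probability proportional to
$e^{-\lambda j}(S-1)^j\binom{K}{j}$, then a uniform position subset, then
uniform substitute symbols).

* `block_hb_sweep()` — the blocked scheme: fresh uniformly-random blocks of
  size `K` each sweep, then per block `u_i <- ball(x_i)` and
  `x_i <- p(x_i | X_-i, theta, u_i, y)` restricted to the ball around
  `u_i`. `block_gibbs_sweep()` is its `m = K` special case, kept
  first-class so Gibbs baselines with small blocks are one call.
* `hb_gibbs_iteration()` — the auxiliary-variable Gibbs scheme
  `U <- p(U|X)`, `theta <- p(theta|X, y)`, `X <- p(X|theta, U, y)`.
* `hb_marginal_mh_iteration()` — the marginal scheme: `theta` is proposed
  and accepted with the ratio of ball-restricted marginals
  $\tilde p(\theta, \mathbf U, \mathbf y)$, with **X** redrawn jointly on
  acceptance. The simplified two-factor acceptance ratio is checked in the
  tests against the unsimplified four-factor ratio to $10^{-10}$.
* `msss_iteration()` — Metropolized Shotgun Stochastic Search, the pure
  Metropolis–Hastings comparator that proposes from the sliced posterior
  and accepts with $\min\{1, Z_m(\mathbf X)/Z_m(\mathbf X')\}$; it reaches
  at most $mP$ entries per iteration, half the auxiliary scheme's reach.
* `random_radius_iteration()` — per-block radii drawn fresh from a
  user-supplied distribution $p(\mathbf m)$; the degenerate distribution
  that frees one block and freezes the rest recovers single-block Gibbs.
  No canonical $p(\mathbf m)$ exists, so the kernel takes it as a function
  argument rather than fixing a family.

Weight arithmetic is done in log space with max-subtraction; a candidate at
log-weight $-\infty$ is legal with probability zero, and a slice whose
candidates are all impossible raises an error rather than silently
resampling. Draws use inverse-CDF on the normalised weights. All
randomness flows from a single seed through R's RNG, so chains are
bit-reproducible.

## The three worked models

**Toy spike regression** (`model_toy`): responses are a known-coefficient
sum of included covariates plus Gaussian noise of known variance; only the
binary inclusion vector is unknown. The generator builds ten uniform
covariates and ten exact replicas, with the signal in covariate 6, so
covariates 6 and 16 form two perfectly symmetric modes. With the whole
vector as one block ($P = 1$, $K = D$, $m = 1$) the sampler switches modes
freely even at noise variance 0.5, while single-site Gibbs — at the same
per-sweep cost — records zero switches there. "Mode occupancy" is defined
as which of the two replicas is included when exactly one is; iterations
with both or neither belong to no mode. This definition is needed to
*count* switches, which are otherwise only visible pictorially.

**g-prior variable selection** (`model_regression`): a Gaussian linear
model with Zellner g-prior $N(0, g\,(\mathbf Z_x^T\mathbf Z_x)^{-1})$ on
the active coefficients, a vague inverse-gamma prior on the noise variance
and a Beta prior on the inclusion probability, all marginalised
analytically:

$$p(\mathbf y, \mathbf x \mid \cdot) \propto (1+g)^{-D_x/2}
\Gamma(D_x + a_{\pi_0})\,\Gamma(D - D_x + b_{\pi_0})
\left[2b_\sigma + S(\mathbf x)\right]^{-(2a_\sigma + N - 1)/2},$$

with $S(\mathbf x) = \mathbf y^T\mathbf y - \tfrac{g}{1+g}\,
\mathbf y^T \mathbf Z_x(\mathbf Z_x^T\mathbf Z_x)^{-1}\mathbf Z_x^T
\mathbf y$. Defaults $g = N$, $a_\sigma = b_\sigma = 0.1$,
$a_{\pi_0} = 0.001$, $b_{\pi_0} = 1$ favour sparse models. The $N-1$
exponent reflects the centred-response convention (responses are centred,
absorbing an intercept). Two numerical decisions matter:

* *Rank rule.* The g-prior is undefined when $\mathbf Z_x^T\mathbf Z_x$ is
  singular — reachable in the duplicated designs, where including both
  members of a replica pair is exactly singular. Such states get zero
  posterior mass ($-\infty$ log weight), declared on Cholesky failure or a
  squared diagonal condition ratio above $10^{10}$. This keeps the target
  well-defined and is consistent with the observed 0.5/0.5 switching
  between replicas: the sampler can hold either replica, never both.
* *Caching.* The sweep (compiled, RcppArmadillo) factorises the
  out-of-block Gram submatrix once per block and extends the Cholesky
  factor by each candidate's columns, never refactorising from scratch;
  the tests verify agreement with the plain-R from-scratch marginal to
  $10^{-8}$.

The sampler follows the blocked scheme with random re-partitioning every
sweep (also for the `m = K` Gibbs baselines, for consistency); the trace
stores the sparse support set, since `D` can be in the thousands. Only
likelihood ratios across inclusion vectors matter, so the additive log
constant is arbitrary.

**Tumor subclonal deconvolution** (`model_deconv`): variant reads at locus
$i$ are Binomial$(d_i, \phi_i)$ with
$\phi_i = (1-e)p_i + e(1-p_i)$ and $p_i = \tfrac12\sum_k \theta_k X_{ki}$:
a mixture of $K$ subclone genotypes (columns of a binary matrix) weighted
by tumor fractions $\theta$ on the simplex. Weights are represented through
independent Gamma$(\alpha/K, 1)$ variables $\gamma_k$ sampled on the log
scale; $\alpha \le 1$ shrinks unused components, giving automatic selection
of the number of subclones. Genotype columns carry Bernoulli$(f_i)$ priors
with conjugate Beta$(f_\alpha, f_\beta)$ frequencies. One iteration runs:

1. columnwise refresh of the auxiliary matrix **U** within the ball,
2. a joint Metropolis–Hastings update of $(v, \mathbf X)$: each $v_k$
   proposed from the mixture $(1-\epsilon)\,N(v_k, \sigma_v^2) +
   \epsilon\,\text{LogGamma}(\alpha/K, 1)$, accepted via the ratio of
   ball-restricted marginals (the genotype prior $p(\mathbf x_i \mid f_i)$
   is included inside the per-column ball sums so that the marginalised
   quantity is the exact conditional target), with all columns of
   **X** redrawn on acceptance,
3. a conjugate Beta update of the mutation frequencies $f$.

The iteration order is a design choice; the three updates each leave the
augmented target invariant, so any order is valid. The Hastings correction
for the mixture proposal marginalises the mixture indicator — evaluating
the full mixture density at the proposed point — which is valid without
augmenting the state. The proposal variance is tuned every 100 iterations
during the first 1,000 burn-in iterations towards a 10–40% acceptance
rate, clipped to $[0.01, 10]$, and frozen afterwards so the stationary
distribution is untouched. Ball sums are computed over a precomputed
$2^K$-state column table (the implementation caps $K$ at 14), with the
current weight table cached so each iteration builds only the proposed
one. Multi-sample data share one genotype matrix while each sample carries
its own weights; the single-sample model is simply the $S = 1$ case of the
same code path, and all samples' weight vectors are proposed and accepted
jointly (whether to update them jointly or per sample is not canonical;
joint updates were chosen for simplicity and exactness of the restricted
marginal).

Reported summaries — max $\theta$, fitted $\phi$, residuals $r/d -
\bar\phi$ — are invariant under permutation of component labels, so label
switching is harmless.

## Synthetic data

The generators are first-class, seeded, and ship a truth sidecar:

* `gen_toy()` — 200 observations, 20 covariates, second half exact replicas
  of the first, signal in covariate 6, noise variance in {0.5, 2, 5}.
* `gen_regression()` — a 100 × 600 design uniform on {0, 1, 2} (SNP dosage
  coding), signal in covariate 11 with noise sd 0.1, then columnwise
  duplication to 100 × 1200.
* `gen_tumor()` — three subclones, weights (0.3, 0.3, 0.4), nested
  (linear-phylogeny) genotypes over nine variants, depth 800. With
  `fresh = FALSE` it returns the frozen reference draw of counts
  (405, 397, 393, 239, 245, 247, 123, 121, 123) — a single stochastic
  realisation shipped as a fixture because no seed can regenerate it —
  and with `fresh = TRUE` new binomial draws. The same allele-frequency
  vector (0.5, 0.3, 0.15 per variant group) is also produced by a branched
  architecture with weights (0.1, 0.6, 0.3), so the posterior is
  genuinely bimodal in max $\theta$ (0.4 vs 0.6); the branched solution is
  derived analytically, and the tests assert bimodality, not its exact
  location.
* `gen_multisample_tumor()` — 17 variants × 13 samples (12 tumor + 1
  normal control) sharing one genotype matrix with per-sample Dirichlet
  weights; the control's weight sits on an unmutated component. The
  generating subclone count, Dirichlet concentration and genotype law are
  package choices of a realistic multi-region design, not reproductions
  of any published dataset.

What the generators emulate is the *structure* that makes these inference
problems hard: exact symmetry between explanations, high depth, sparse
truth. They do not emulate mapping artefacts, overdispersion, copy-number
variation, or locus-dependent error rates, so passing tests demonstrate
correct inference under the stated model, not robustness to real-data
misspecification.

## Diagnostics

`iat()` implements the integrated autocorrelation time with Geyer's
initial-positive-sequence truncation (the estimator is not canonical; this
choice is standard and conservative), clipped below at 1, with ESS
attached; a constant series is reported as IAT = length with a warning.
`mode_switches()` counts transitions between user-defined disjoint mode
predicates, ignoring unassigned iterations. `overall_efficiency()` is the
switch count per unit wall time — reported for ranking only, never
asserted, because it is hardware-dependent. `trace_modes()` segments a
scalar trace at the valleys of its kernel density estimate and reports
peak locations and masses; the deconvolution summaries use it to locate
the linear-architecture mode.

## Problem sizes used by the tests

Stationarity of every kernel is checked against brute-force enumeration on
instances of at most 4,096 joint states ($10^5$–$1.5\times10^5$
iterations, total-variation tolerance 0.02; 0.05 for the joint
parameter-and-state check of the marginal scheme). The duplicated-design
regression check runs the full 100 × 1200 design for 50,000 sweeps in the
test suite and 100,000 sweeps — the paper-scale run length — in the
acceptance script: replica switches occur only when both replicas land in
the same random block (about once per 1,500 sweeps), so the longer run is
what stabilises the 0.5/0.5 inclusion estimate. The deconvolution check
uses 10,000 burn-in plus 20,000 sampling iterations at $m = 4$, where the
ball sums cover 163 of the 256 column states.

## Known limitations

* The generic kernels assume per-block factorised weights for the marginal
  Metropolis–Hastings and M-SSS schemes (or a single block); fully general
  non-factorised joint marginals would require enumerating the product
  ball.
* `enumerate_ball()` and the deconvolution column tables are exponential in
  the block size; the implementation is intended for the $K \lesssim 14$
  regime where the method is designed to operate.
* Radii are fixed during sampling (or drawn from a fixed $p(\mathbf m)$);
  adapting $\mathbf m$ to the local uncertainty of **X** during sampling
  is out of scope.
* No parallelisation of ball sums; sums are cheap at the radii used here.
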