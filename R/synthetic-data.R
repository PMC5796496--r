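#' Simulate the replica-covariate toy regression
#'
#' Generates the mode-switching illustration: `n` observations on `D = 20`
#' covariates where the first ten are uniform on (0, 1) and columns 11-20 are
#' exact replicas of columns 1-10. Responses come from covariate 6 alone with
#' unit coefficient and Gaussian noise, so covariates 6 and 16 give two
#' completely symmetric posterior modes.
#'
#' @param sigma2 Observation noise variance (the study uses 0.5, 2 and 5).
#' @param seed Optional RNG seed (recorded in the output).
#' @param n Number of observations.
#' @param D Number of covariates (even; the second half replicates the first).
#' @return List with `y` (responses), `Z` (design matrix), `sigma2`,
#'   `x_true` (generating inclusion vector) and `seed`.
#' @export
gen_toy <- function(sigma2, seed = NULL, n = 200, D = 20) {
  stopifnot(sigma2 > 0, D %% 2 == 0, D >= 12)
  if (!is.null(seed)) set.seed(seed)
  half <- D / 2
  Z <- matrix(stats::runif(n * half), n, half)
  Z <- cbind(Z, Z)
  y <- Z[, 6] + stats::rnorm(n, 0, sqrt(sigma2))
  x_true <- integer(D)
  x_true[6] <- 1L
  list(y = y, Z = Z, sigma2 = sigma2, x_true = x_true, seed = seed)
}

#' Simulate the duplicated-design sparse regression
#'
#' Builds an `N x D_half` design with entries drawn uniformly from
#' \{0, 1, 2\} (SNP genotype coding), generates responses from covariate 11
#' with unit coefficient and Normal(0, sd^2) noise, then duplicates the
#' design columnwise to an `N x 2*D_half` matrix. Covariates 11 and
#' `D_half + 11` then explain the responses equally well, creating a
#' perfectly symmetric pair of posterior modes.
#'
#' @param seed Optional RNG seed.
#' @param N Number of observations (default 100).
#' @param D_half Number of distinct covariates before duplication
#'   (default 600; final design has `2 * D_half` columns).
#' @param sd Noise standard deviation (default 0.1).
#' @param relevant Index of the generating covariate (default 11).
#' @return List with `y`, `Z`, `x_true`, `relevant` (the two replica
#'   indices), and `seed`.
#' @export
gen_regression <- function(seed = NULL, N = 100, D_half = 600, sd = 0.1,
                           relevant = 11) {
  stopifnot(N >= 2, D_half > relevant)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(sample(0:2, N * D_half, replace = TRUE), N, D_half)
  y <- Z[, relevant] + stats::rnorm(N, 0, sd)
  Z <- cbind(Z, Z)
  x_true <- integer(2 * D_half)
  x_true[relevant] <- 1L
  list(y = y, Z = Z, x_true = x_true,
       relevant = c(relevant, D_half + relevant), seed = seed)
}

# Printed ground truth of the single-sample tumor simulation: three
# subclones in a linear phylogeny, nine variants in three groups of three.
.tumor_truth <- function() {
  X0 <- rbind(rep(1L, 9),
              c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L),
              c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  theta0 <- c(0.3, 0.3, 0.4)
  list(theta0 = theta0, X0 = X0, p0 = as.numeric(0.5 * crossprod(X0, theta0)))
}

#' Simulate (or reproduce) the single-sample tumor read counts
#'
#' The generative truth is three subclones with weights
#' `theta0 = (0.3, 0.3, 0.4)` and a nested (linear-phylogeny) 3 x 9 binary
#' genotype matrix, giving expected variant allele frequencies
#' (0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.15, 0.15, 0.15) at error rate 0.
#' With `fresh = FALSE` the function returns the frozen reference draw of
#' variant-read counts at depth 800 (a single stochastic realisation shipped
#' as a fixture, since a draw cannot be regenerated from an unknown seed);
#' with `fresh = TRUE` new binomial counts are drawn.
#'
#' @param seed Optional RNG seed (used only when `fresh = TRUE`).
#' @param fresh Draw new counts instead of returning the frozen reference
#'   draw?
#' @param depth Sequencing depth per variant (default 800).
#' @return List with `counts` (data frame: `variant_id`, `sample_id`,
#'   `variant_reads`, `depth`), and the truth sidecar `theta0`, `X0`, `p0`,
#'   `seed`.
#' @export
gen_tumor <- function(seed = NULL, fresh = FALSE, depth = 800) {
  tr <- .tumor_truth()
  if (fresh) {
    if (!is.null(seed)) set.seed(seed)
    r <- stats::rbinom(9, depth, tr$p0)
  } else {
    r <- c(405L, 397L, 393L, 239L, 245L, 247L, 123L, 121L, 123L)
    depth <- 800
  }
  counts <- data.frame(variant_id = paste0("v", 1:9),
                       sample_id = "s1",
                       variant_reads = as.integer(r),
                       depth = as.integer(rep(depth, 9)))
  list(counts = counts, theta0 = tr$theta0, X0 = tr$X0, p0 = tr$p0,
       seed = if (fresh) seed else NULL)
}

#' Simulate a multi-sample tumor read-count table
#'
#' Emulates a multi-region sequencing design: a single shared binary
#' genotype matrix over `K0` subclones and `n_variants` variants, with each
#' tumor sample carrying its own Dirichlet-distributed subclone weights. One
#' sample is a normal-tissue control whose weight sits entirely on an
#' unmutated component, so its expected variant allele frequencies equal the
#' error rate.
#'
#' @param S Total number of samples including the normal control
#'   (default 13: 12 tumor + 1 normal).
#' @param seed Optional RNG seed.
#' @param n_variants Number of variants (default 17).
#' @param K0 Number of generating subclones, including the unmutated
#'   component (default 4).
#' @param depth Sequencing depth (default 800).
#' @param e Sequencing error rate used in the generative VAF (default 0.01).
#' @param alpha0 Dirichlet concentration for tumor-sample weights.
#' @return List with `counts` (long-format data frame) and the truth sidecar
#'   `X0`, `theta0` (`K0 x S`), `phi0` (`n_variants x S`), `seed`.
#' @export
gen_multisample_tumor <- function(S = 13, seed = NULL, n_variants = 17,
                                  K0 = 4, depth = 800, e = 0.01,
                                  alpha0 = 2) {
  stopifnot(S >= 2, K0 >= 2)
  if (!is.null(seed)) set.seed(seed)
  # component 1 is the unmutated (normal) genotype
  X0 <- rbind(integer(n_variants),
              matrix(stats::rbinom((K0 - 1) * n_variants, 1, 0.5),
                     K0 - 1, n_variants))
  # ensure every variant is carried by at least one subclone
  empty <- colSums(X0) == 0
  if (any(empty)) X0[K0, empty] <- 1L
  theta0 <- matrix(0, K0, S)
  theta0[1, S] <- 1  # final sample is the normal control
  for (s in seq_len(S - 1)) {
    g <- stats::rgamma(K0 - 1, alpha0, 1)
    theta0[-1, s] <- g / sum(g)
  }
  p0 <- 0.5 * crossprod(X0, theta0)          # n_variants x S
  phi0 <- (1 - e) * p0 + e * (1 - p0)
  r <- matrix(stats::rbinom(n_variants * S, depth, phi0), n_variants, S)
  counts <- data.frame(
    variant_id = rep(paste0("v", seq_len(n_variants)), times = S),
    sample_id = rep(c(paste0("t", seq_len(S - 1)), "normal"),
                    each = n_variants),
    variant_reads = as.integer(r),
    depth = as.integer(rep(depth, n_variants * S)))
  list(counts = counts, X0 = X0, theta0 = theta0, phi0 = phi0, seed = seed)
}
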