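#' Hyperparameters for the g-prior sparse regression
#'
#' Defaults follow the vague-prior convention used throughout: inverse-gamma
#' `(0.1, 0.1)` on the noise variance, `g = N` for the Zellner g-prior scale,
#' and a Beta`(0.001, 1)` prior on the inclusion probability, which strongly
#' favours sparse configurations.
#'
#' @param N Sample size (used for the default `g = N`).
#' @param g g-prior scale.
#' @param a_sigma,b_sigma Inverse-gamma shape and rate for the noise
#'   variance.
#' @param a_pi0,b_pi0 Beta hyperparameters for the prior inclusion
#'   probability.
#' @return List of hyperparameters.
#' @export
regression_hyper <- function(N, g = N, a_sigma = 0.1, b_sigma = 0.1,
                             a_pi0 = 0.001, b_pi0 = 1) {
  stopifnot(g > 0, a_sigma > 0, b_sigma > 0, a_pi0 > 0, b_pi0 > 0)
  list(g = g, a_sigma = a_sigma, b_sigma = b_sigma,
       a_pi0 = a_pi0, b_pi0 = b_pi0)
}

#' Marginal log posterior of an inclusion vector
#'
#' With the regression coefficients, noise variance and prior inclusion
#' probability integrated out analytically, the joint density of the
#' (centred) responses and an inclusion vector `x` is
#' \deqn{p(y, x \mid \cdot) \propto (1+g)^{-D_x/2}
#'   \Gamma(D_x + a_{\pi_0}) \Gamma(D - D_x + b_{\pi_0})
#'   \left[2 b_\sigma + S(x)\right]^{-(2 a_\sigma + N - 1)/2},}
#' where \eqn{D_x = \sum_d x_d} and
#' \eqn{S(x) = y^T y - \frac{g}{1+g} y^T Z_x (Z_x^T Z_x)^{-1} Z_x^T y}.
#' The additive log constant is arbitrary (only ratios across `x` matter).
#' A rank-deficient \eqn{Z_x^T Z_x} -- e.g. both members of a duplicated
#' column pair included, or \eqn{D_x > N} -- makes the g-prior undefined and
#' returns `-Inf` (zero posterior mass). Singularity is declared on Cholesky
#' failure or a squared diagonal condition ratio above `1e10`.
#'
#' @param x Binary inclusion vector of length `ncol(data$Z)`.
#' @param data List with `y` (centred responses) and design matrix `Z`.
#' @param hyper Hyperparameters from [regression_hyper()].
#' @return Scalar log marginal (up to a constant), possibly `-Inf`.
#' @export
log_marginal <- function(x, data, hyper) {
  stopifnot(length(x) == ncol(data$Z))
  act <- which(x == 1)
  N <- length(data$y)
  D <- ncol(data$Z)
  yty <- sum(data$y^2)
  S <- yty
  if (length(act) > 0) {
    Zx <- data$Z[, act, drop = FALSE]
    R <- tryCatch(chol(crossprod(Zx)), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    dg <- diag(R)
    if (min(dg) <= 0 || (max(dg) / min(dg))^2 > 1e10) return(-Inf)
    w <- backsolve(R, crossprod(Zx, data$y), transpose = TRUE)
    S <- max(0, yty - hyper$g / (1 + hyper$g) * sum(w^2))
  }
  k <- length(act)
  -0.5 * k * log(1 + hyper$g) + lgamma(k + hyper$a_pi0) +
    lgamma(D - k + hyper$b_pi0) -
    0.5 * (2 * hyper$a_sigma + N - 1) * log(2 * hyper$b_sigma + S)
}

#' Block Hamming ball sampler for g-prior variable selection
#'
#' Runs the blocked sweep over the marginal posterior of the inclusion
#' vector: each iteration re-partitions the `D` covariates into `P = D/K`
#' random blocks and, per block, draws an auxiliary block uniformly in the
#' Hamming ball around the current block, then redraws the block from the
#' ball around the auxiliary block with weights proportional to the
#' marginal joint density. `m = K` gives the standard block Gibbs baselines
#' (BG-K); `K = 10` with `m` in 1..3 gives the HB1-HB3 schemes. The sweep is
#' implemented in compiled code; responses are centred (optionally
#' standardised) before sampling.
#'
#' @param data List with `y` and `Z` (as from [gen_regression()] or
#'   [load_regression_data()]).
#' @param hyper Hyperparameters; default [regression_hyper()] with `g = N`.
#' @param K Block size (default 10).
#' @param m Hamming ball radius, `1 <= m <= K` (default 1).
#' @param iterations Post-burn-in sweeps to record (default 100000).
#' @param burn_in Burn-in sweeps (default 100).
#' @param seed RNG seed.
#' @param thin Keep every `thin`-th support set in the trace (inclusion
#'   probabilities always use every post-burn-in sweep).
#' @param scale_y Also scale the centred responses to unit variance?
#' @param init Optional initial support (integer covariate indices);
#'   default is a random sparse initialisation.
#' @return Object of class `regression_chain`: list with `inclusion`
#'   (per-covariate posterior inclusion probabilities), `support` (list of
#'   recorded support sets), `logml` (log marginal trace), `n_kept`,
#'   `n_evals` (total candidate marginal evaluations), `config`, `seed`.
#' @export
regression_block_hb <- function(data, hyper = NULL, K = 10, m = 1,
                                iterations = 100000, burn_in = 100,
                                seed = NULL, thin = 1, scale_y = FALSE,
                                init = NULL) {
  N <- length(data$y)
  D <- ncol(data$Z)
  stopifnot(K >= 1, K <= D, m >= 1, m <= K)
  if (is.null(hyper)) hyper <- regression_hyper(N)
  y <- data$y - mean(data$y)
  if (scale_y) y <- y / stats::sd(y)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    init <- sample.int(D, min(D, max(1, stats::rbinom(1, D, 1 / D))))
  }
  G <- crossprod(data$Z)
  zty <- as.numeric(crossprod(data$Z, y))
  res <- cpp_regression_block_hb(G, zty, sum(y^2), N, D, hyper$g,
                                 hyper$a_sigma, hyper$b_sigma, hyper$a_pi0,
                                 hyper$b_pi0, as.integer(K), as.integer(m),
                                 as.integer(iterations), as.integer(burn_in),
                                 as.integer(thin), as.integer(init))
  structure(c(res, list(config = list(K = K, m = m, iterations = iterations,
                                      burn_in = burn_in, thin = thin,
                                      hyper = hyper, scale_y = scale_y),
                        D = D, seed = seed)),
            class = "regression_chain")
}

#' Posterior inclusion probabilities from a regression chain
#'
#' Per-covariate posterior mean of the inclusion indicator over the
#' post-burn-in sweeps. With `running = TRUE` returns the cumulative
#' (running) inclusion probabilities for the requested covariates, the
#' quantity plotted in mixing-diagnostic trace plots.
#'
#' @param chain A `regression_chain` from [regression_block_hb()].
#' @param indices Covariate indices for the running version (required when
#'   `running = TRUE`; thinned trace resolution).
#' @param running Return running means instead of final probabilities?
#' @return Numeric vector of length `D`, or a matrix (iterations x
#'   `length(indices)`) of running means.
#' @export
inclusion_probabilities <- function(chain, indices = NULL, running = FALSE) {
  if (!running) return(chain$inclusion)
  if (is.null(indices)) {
    stop("inclusion_probabilities(): running = TRUE needs covariate indices")
  }
  ind <- vapply(chain$support, function(s) as.numeric(indices %in% s),
                numeric(length(indices)))
  ind <- matrix(ind, ncol = length(indices), byrow = TRUE)
  out <- apply(ind, 2, cumsum) / seq_len(nrow(ind))
  colnames(out) <- as.character(indices)
  out
}

#' @export
print.regression_chain <- function(x, ...) {
  cat("Block Hamming ball regression chain (K =", x$config$K,
      ", m =", x$config$m, ")\n")
  cat("  sweeps recorded:", x$n_kept, "\n")
  top <- order(x$inclusion, decreasing = TRUE)[1:5]
  cat("  top covariates: ",
      paste0(top, " (", round(x$inclusion[top], 3), ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' Screen covariates by response correlation
#'
#' Data-preparation utility for large genotype panels: flags covariates
#' whose absolute Pearson correlation with the response exceeds a threshold
#' (default 0.3), the screening rule used to assemble eQTL covariate panels.
#'
#' @param y Response vector.
#' @param Z Design matrix.
#' @param threshold Absolute-correlation threshold.
#' @return Logical vector, `TRUE` for covariates exceeding the threshold.
#' @export
correlation_screen <- function(y, Z, threshold = 0.3) {
  abs(as.numeric(stats::cor(Z, y))) > threshold
}
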