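#' Hyperparameters and sampler settings for tumor subclonal deconvolution
#'
#' The mixture has `K` candidate subclones with Dirichlet(`alpha/K`, ...,
#' `alpha/K`) weights (represented through independent Gamma variables;
#' `alpha <= 1` shrinks unused component weights towards zero, giving
#' automatic selection of the number of subclones), Beta(`f_alpha`,
#' `f_beta`) priors on per-variant mutation frequencies, and a sequencing
#' error rate `e`. Sampler settings: Hamming ball radius `m` over genotype
#' columns, mixture-proposal weight `epsilon`, and initial random-walk
#' variance `sigma_v2` (tuned during burn-in to a 10-40% acceptance rate and
#' clipped to `[0.01, 10]`).
#'
#' @param K Number of mixture components (default 8).
#' @param alpha Dirichlet concentration (default 1).
#' @param f_alpha,f_beta Beta hyperparameters for mutation frequencies
#'   (default 0.5, 0.5).
#' @param e Sequencing error rate in `[0, 0.5)` (default 0.01).
#' @param m Hamming ball radius over the `K`-long genotype columns
#'   (default 4; `m = K` gives the fully marginalised sampler).
#' @param epsilon Prior-component weight of the mixture proposal
#'   (default 0.01).
#' @param sigma_v2 Initial random-walk proposal variance (default 1).
#' @return List of settings.
#' @export
deconv_hyper <- function(K = 8, alpha = 1, f_alpha = 0.5, f_beta = 0.5,
                         e = 0.01, m = 4, epsilon = 0.01, sigma_v2 = 1) {
  stopifnot(K >= 1, alpha > 0, f_alpha > 0, f_beta > 0,
            e >= 0, e < 0.5, m >= 0, m <= K,
            epsilon >= 0, epsilon <= 1, sigma_v2 >= 0.01, sigma_v2 <= 10)
  list(K = as.integer(K), alpha = alpha, f_alpha = f_alpha, f_beta = f_beta,
       e = e, m = as.integer(m), epsilon = epsilon, sigma_v2 = sigma_v2)
}

#' Expected variant allele frequency
#'
#' Each variant's expected fraction of variant reads:
#' `phi_i = (1 - e) p_i + e (1 - p_i)` with `p_i = (1/2) sum_k theta_k X_ki`
#' (heterozygous mutations in diploid genomes contribute half their carrier
#' fraction). For `theta` a matrix (one column per sample sharing the same
#' genotype matrix), a variant-by-sample matrix is returned.
#'
#' @param theta Mixture weight vector of length `K` (or `K x S` matrix).
#' @param X Binary `K x N` genotype matrix (subclones by variants).
#' @param e Sequencing error rate.
#' @return Numeric vector of length `N` (or `N x S` matrix), entries in
#'   `[e, 1 - e]` when weights lie on the simplex.
#' @export
vaf <- function(theta, X, e) {
  p <- 0.5 * crossprod(X, theta)
  out <- (1 - e) * p + e * (1 - p)
  if (is.matrix(theta)) out else as.numeric(out)
}

#' Binomial read-count log likelihood
#'
#' `sum_i log Binomial(r_i | d_i, phi_i)` including the binomial
#' coefficient, so the value is a proper log density.
#'
#' @param r Variant-read counts.
#' @param d Total depths.
#' @param phi Variant allele frequencies in `[0, 1]`.
#' @return Scalar log likelihood (`-Inf` when some `phi_i` is 0 or 1 but the
#'   counts are incompatible).
#' @export
deconv_log_lik <- function(r, d, phi) {
  stopifnot(length(r) == length(d), length(r) == length(phi))
  sum(stats::dbinom(r, d, phi, log = TRUE))
}

# log density of v = log(gamma), gamma ~ Gamma(shape, 1) (the log-gamma
# distribution): shape * v - exp(v) - log Gamma(shape), per component.
.dloggamma <- function(v, shape) {
  shape * v - exp(v) - lgamma(shape)
}

#' Log prior density of the log-gamma weight variables
#'
#' The mixture weights are `theta_k = gamma_k / sum_j gamma_j` with
#' `gamma_k ~ Gamma(alpha/K, 1)`; the sampler works with `v_k = log gamma_k`,
#' whose density (by change of variables) is
#' `(alpha/K) v_k - exp(v_k) - log Gamma(alpha/K)` per component.
#'
#' @param v Real vector (or matrix) of log-gamma variables.
#' @param alpha Dirichlet concentration.
#' @param K Number of components.
#' @return Scalar log prior density.
#' @export
log_prior_v <- function(v, alpha, K) {
  sum(.dloggamma(v, alpha / K))
}

# ---- internal sampler machinery -------------------------------------------

# Long-format counts table -> matrices (variants x samples), keeping order
# of first appearance.
.counts_matrices <- function(counts) {
  stopifnot(all(c("variant_id", "sample_id", "variant_reads", "depth")
                %in% names(counts)))
  vids <- unique(counts$variant_id)
  sids <- unique(counts$sample_id)
  r <- matrix(NA_integer_, length(vids), length(sids),
              dimnames = list(vids, sids))
  d <- r
  iv <- match(counts$variant_id, vids)
  is <- match(counts$sample_id, sids)
  r[cbind(iv, is)] <- counts$variant_reads
  d[cbind(iv, is)] <- counts$depth
  if (anyNA(r) || anyNA(d)) {
    stop("counts table is not a complete variant x sample grid")
  }
  list(r = r, d = d, variant_ids = vids, sample_ids = sids)
}

# Precompute the full 2^K column-state space, per-state popcounts, and the
# Hamming ball index sets for radius m.
.deconv_ctx <- function(r, d, hyper) {
  K <- hyper$K
  if (K > 14) stop("deconv sampler: K > 14 would enumerate > 2^14 column states")
  # row index s corresponds to the binary encoding with component 1 as the
  # least-significant bit, matching .encode_cols()
  states <- as.matrix(expand.grid(rep(list(0:1), K)))
  dimnames(states) <- NULL
  storage.mode(states) <- "integer"
  nones <- rowSums(states)
  dist <- tcrossprod(states, 1L - states)
  dist <- dist + t(dist)
  ball <- apply(dist <= hyper$m, 1, which, simplify = FALSE)
  list(r = r, d = d, N = nrow(r), S = ncol(r), K = K, e = hyper$e,
       states = states, nones = nones, ball = ball,
       lconst = sum(lchoose(d, r)))
}

.encode_cols <- function(ctx, X) {
  as.integer(1L + crossprod(X, 2L^(0:(ctx$K - 1L))))
}

# 2^K x N table of log p(y_i | column state, theta) summed over samples
# (each sample with its own theta column), including binomial coefficients.
.loglik_table <- function(ctx, theta) {
  theta <- matrix(theta, ctx$K, ctx$S)
  LL <- matrix(0, nrow(ctx$states), ctx$N)
  for (s in seq_len(ctx$S)) {
    p <- as.numeric(0.5 * (ctx$states %*% theta[, s]))
    phi <- (1 - ctx$e) * p + ctx$e * (1 - p)
    phi <- pmin(pmax(phi, 1e-300), 1 - 1e-16)
    LL <- LL + outer(log(phi), ctx$r[, s]) +
      outer(log1p(-phi), ctx$d[, s] - ctx$r[, s])
  }
  LL + ctx$lconst / ctx$N  # spread the constant; total matches the density
}

# 2^K x N table of log p(column state | f_i)
.prior_table <- function(ctx, f) {
  outer(ctx$nones, log(f)) + outer(ctx$K - ctx$nones, log1p(-f))
}

# sum_i log sum_{x_i in ball(u_i)} exp(W[x_i, i])
.restricted_colsum <- function(ctx, W, u_idx) {
  tot <- 0
  for (i in seq_len(ctx$N)) {
    w <- W[ctx$ball[[u_idx[i]]], i]
    mx <- max(w)
    tot <- tot + if (is.finite(mx)) mx + log(sum(exp(w - mx))) else -Inf
  }
  tot
}

.theta_from_v <- function(v, K, S) {
  v <- matrix(v, K, S)
  g <- exp(v)
  sweep(g, 2, colSums(g), "/")
}

# ---- exported single-step operations --------------------------------------

#' Restricted log marginal of the weight variables
#'
#' The log of the model weight summed over all genotype matrices within the
#' Hamming ball (radius `hyper$m`, columnwise) around the auxiliary matrix
#' `U`:
#' `sum_i log sum_{x_i in H_m(u_i)} p(y_i | x_i, theta(v)) p(x_i | f_i)`
#' plus the log-gamma prior of `v`. The ball sums factorise over the `N`
#' genotype columns. With `m = K` this is the fully marginalised
#' `log p(v, f, y)`; with `m = 0` it reduces to the single term at `U`.
#'
#' @param v Log-gamma weight variables (`K`-vector, or `K x S` matrix for
#'   multi-sample data).
#' @param U Binary `K x N` auxiliary genotype matrix.
#' @param counts Read-count table (data frame with `variant_id`,
#'   `sample_id`, `variant_reads`, `depth`).
#' @param f Per-variant mutation frequencies (length `N`).
#' @param hyper Settings from [deconv_hyper()].
#' @return Scalar log marginal.
#' @export
restricted_log_marginal <- function(v, U, counts, f, hyper) {
  cm <- .counts_matrices(counts)
  ctx <- .deconv_ctx(cm$r, cm$d, hyper)
  theta <- .theta_from_v(v, ctx$K, ctx$S)
  W <- .loglik_table(ctx, theta) + .prior_table(ctx, f)
  .restricted_colsum(ctx, W, .encode_cols(ctx, U)) +
    log_prior_v(v, hyper$alpha, hyper$K)
}

#' Joint Metropolis-Hastings update of weights and genotypes
#'
#' Proposes each `v_k` from the mixture `(1 - epsilon) Normal(v_k, sigma_v2)
#' + epsilon LogGamma(alpha/K, 1)`, accepts jointly via the ratio of
#' restricted log marginals (all genotype matrices in the ball around `U`
#' summed out) times the Hastings correction for the mixture proposal, and
#' on acceptance redraws every genotype column from its normalised ball
#' weights under the new weights. On rejection the state is kept unchanged.
#'
#' @param v,X,f Current state: log-gamma variables (`K` or `K x S`), binary
#'   `K x N` genotype matrix, per-variant mutation frequencies.
#' @param U Current auxiliary genotype matrix.
#' @param counts Read-count table (long-format data frame).
#' @param hyper Settings from [deconv_hyper()].
#' @param sigma_v2 Random-walk proposal variance (defaults to
#'   `hyper$sigma_v2`).
#' @return List with updated `v`, `X`, `theta` and logical `accepted`.
#' @export
mh_theta_X_update <- function(v, X, f, U, counts, hyper,
                              sigma_v2 = hyper$sigma_v2) {
  cm <- .counts_matrices(counts)
  ctx <- .deconv_ctx(cm$r, cm$d, hyper)
  st <- list(v = matrix(v, ctx$K, ctx$S), X = X, f = f,
             u_idx = .encode_cols(ctx, U))
  PX <- .prior_table(ctx, f)
  st$W <- .loglik_table(ctx, .theta_from_v(st$v, ctx$K, ctx$S)) + PX
  res <- .deconv_mh_step(ctx, st, PX, hyper, sigma_v2)
  list(v = res$st$v, X = res$st$X,
       theta = .theta_from_v(res$st$v, ctx$K, ctx$S),
       accepted = res$accepted)
}

# One joint (v, X) M-H step given cached weight table st$W for the current
# v; returns updated state and its weight table.
.deconv_mh_step <- function(ctx, st, PX, hyper, sigma_v2) {
  shape <- hyper$alpha / hyper$K
  eps <- hyper$epsilon
  n_v <- length(st$v)
  from_prior <- stats::runif(n_v) < eps
  v_new <- st$v + sqrt(sigma_v2) * stats::rnorm(n_v)
  if (any(from_prior)) {
    v_new[from_prior] <- log(stats::rgamma(sum(from_prior), shape, 1))
  }
  v_new <- matrix(v_new, ctx$K, ctx$S)
  lq <- function(to, from) {
    sum(log((1 - eps) * stats::dnorm(to, from, sqrt(sigma_v2)) +
              eps * exp(.dloggamma(to, shape))))
  }
  W_new <- .loglik_table(ctx, .theta_from_v(v_new, ctx$K, ctx$S)) + PX
  lm_cur <- .restricted_colsum(ctx, st$W, st$u_idx) +
    log_prior_v(st$v, hyper$alpha, hyper$K)
  lm_new <- .restricted_colsum(ctx, W_new, st$u_idx) +
    log_prior_v(v_new, hyper$alpha, hyper$K)
  lr <- lm_new - lm_cur + lq(st$v, v_new) - lq(v_new, st$v)
  accepted <- is.finite(lm_new) && log(stats::runif(1)) < lr
  if (accepted) {
    st$v <- v_new
    st$W <- W_new
    for (i in seq_len(ctx$N)) {
      bi <- ctx$ball[[st$u_idx[i]]]
      w <- W_new[bi, i]
      w <- exp(w - max(w))
      st$X[, i] <- ctx$states[bi[.draw_categorical(w / sum(w))], ]
    }
  }
  list(st = st, accepted = accepted)
}

#' Gibbs update of the per-variant mutation frequencies
#'
#' Conjugate Beta draw per variant:
#' `f_i ~ Beta(f_alpha + sum_k X_ki, f_beta + K - sum_k X_ki)`.
#'
#' @param X Binary `K x N` genotype matrix.
#' @param hyper Settings from [deconv_hyper()].
#' @return Numeric vector of `N` sampled frequencies.
#' @export
gibbs_f_update <- function(X, hyper) {
  ones <- colSums(X)
  stats::rbeta(ncol(X), hyper$f_alpha + ones, hyper$f_beta + hyper$K - ones)
}

#' Adapt the random-walk proposal variance
#'
#' Multiplicative adjustment towards a 10-40% acceptance band, hard-clipped
#' to `[0.01, 10]`. Used only during the tuning phase of burn-in; the
#' variance is frozen afterwards so the stationary distribution is exact.
#'
#' @param sigma_v2 Current proposal variance.
#' @param accept_rate Acceptance rate over the last tuning window.
#' @return Updated proposal variance.
#' @export
tune_proposal <- function(sigma_v2, accept_rate) {
  if (accept_rate < 0.1) sigma_v2 <- sigma_v2 / 2
  else if (accept_rate > 0.4) sigma_v2 <- sigma_v2 * 2
  min(10, max(0.01, sigma_v2))
}

#' Marginal Hamming ball sampler for tumor subclonal deconvolution
#'
#' Fits the binomial mixture by Metropolis-within-Gibbs with the marginal
#' Hamming ball construction: per iteration (i) the auxiliary genotype
#' matrix `U` is redrawn columnwise, uniformly within the Hamming ball
#' around each genotype column; (ii) the log-weight variables `v` (hence
#' the mixture weights `theta`) and the full genotype matrix `X` are updated
#' by a joint Metropolis-Hastings step whose acceptance ratio sums all
#' genotype matrices inside the ball around `U` out of the target; (iii)
#' the mutation frequencies `f` get a conjugate Beta Gibbs update. Works
#' unchanged for multi-sample tables, where all samples share `X` but carry
#' their own weights `theta_s` (proposed and accepted jointly).
#'
#' @param counts Long-format read-count table: `variant_id`, `sample_id`,
#'   `variant_reads`, `depth` (one `sample_id` for single-sample data).
#' @param hyper Settings from [deconv_hyper()].
#' @param iterations Post-burn-in iterations to record (default 20000).
#' @param burn_in Burn-in iterations (default 10000).
#' @param tune_iters Initial tuning-phase length within burn-in during which
#'   `sigma_v2` adapts every 100 iterations (default 1000).
#' @param seed RNG seed.
#' @param thin Record every `thin`-th iteration.
#' @return Object of class `deconv_fit`: `max_theta` (iterations x samples),
#'   `theta` (iterations x K x samples array), `phi_mean` (posterior mean
#'   variant allele frequencies, variants x samples), `f_mean`,
#'   `accept_rate`, `sigma_v2` (tuned value), `X_last`, `v_last`,
#'   `variant_ids`, `sample_ids`, `r`, `d`, `config`, `seed`.
#' @export
deconv_hb <- function(counts, hyper = deconv_hyper(), iterations = 20000,
                      burn_in = 10000, tune_iters = 1000, seed = NULL,
                      thin = 1) {
  if (!is.null(seed)) set.seed(seed)
  cm <- .counts_matrices(counts)
  ctx <- .deconv_ctx(cm$r, cm$d, hyper)
  K <- ctx$K; N <- ctx$N; S <- ctx$S
  # initial state
  v <- matrix(log(stats::rgamma(K * S, 1, 1)), K, S)
  X <- matrix(stats::rbinom(K * N, 1, 0.5), K, N)
  f <- stats::rbeta(N, hyper$f_alpha, hyper$f_beta)
  PX <- .prior_table(ctx, f)
  st <- list(v = v, X = X, f = f, u_idx = .encode_cols(ctx, X),
             W = .loglik_table(ctx, .theta_from_v(v, K, S)) + PX)
  sigma_v2 <- hyper$sigma_v2
  n_keep <- floor(iterations / thin)
  theta_trace <- array(NA_real_, c(n_keep, K, S))
  max_theta <- matrix(NA_real_, n_keep, S)
  phi_sum <- matrix(0, N, S)
  f_sum <- numeric(N)
  n_acc <- 0L; n_post <- 0L; kept <- 0L
  win_acc <- 0L; win_n <- 0L
  total <- burn_in + iterations
  for (t in seq_len(total)) {
    # (i) refresh auxiliary matrix columnwise within the ball around X
    x_idx <- .encode_cols(ctx, st$X)
    st$u_idx <- vapply(x_idx, function(s) {
      b <- ctx$ball[[s]]
      b[sample.int(length(b), 1L)]
    }, integer(1))
    # (ii) joint (v, X) marginal Hamming ball M-H step
    res <- .deconv_mh_step(ctx, st, PX, hyper, sigma_v2)
    st <- res$st
    win_acc <- win_acc + res$accepted; win_n <- win_n + 1L
    # (iii) conjugate update of mutation frequencies
    st$f <- gibbs_f_update(st$X, hyper)
    PX_new <- .prior_table(ctx, st$f)
    st$W <- st$W - PX + PX_new
    PX <- PX_new
    if (t <= tune_iters && t %% 100 == 0) {
      sigma_v2 <- tune_proposal(sigma_v2, win_acc / win_n)
      win_acc <- 0L; win_n <- 0L
    }
    if (t == burn_in) { win_acc <- 0L; win_n <- 0L }
    if (t > burn_in) {
      n_post <- n_post + 1L
      n_acc <- n_acc + res$accepted
      theta <- .theta_from_v(st$v, K, S)
      phi_sum <- phi_sum + vaf(theta, st$X, hyper$e)
      f_sum <- f_sum + st$f
      if (n_post %% thin == 0L) {
        kept <- kept + 1L
        theta_trace[kept, , ] <- theta
        max_theta[kept, ] <- apply(theta, 2, max)
      }
    }
  }
  structure(list(max_theta = max_theta[seq_len(kept), , drop = FALSE],
                 theta = theta_trace[seq_len(kept), , , drop = FALSE],
                 phi_mean = phi_sum / n_post,
                 f_mean = f_sum / n_post,
                 accept_rate = n_acc / n_post,
                 sigma_v2 = sigma_v2,
                 X_last = st$X, v_last = st$v,
                 variant_ids = cm$variant_ids, sample_ids = cm$sample_ids,
                 r = cm$r, d = cm$d,
                 config = list(hyper = hyper, iterations = iterations,
                               burn_in = burn_in, tune_iters = tune_iters,
                               thin = thin),
                 seed = seed),
            class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat("Hamming ball deconvolution fit (K =", x$config$hyper$K,
      ", m =", x$config$hyper$m, ")\n")
  cat("  variants x samples:", nrow(x$phi_mean), "x", ncol(x$phi_mean), "\n")
  cat("  recorded iterations:", nrow(x$max_theta), "\n")
  cat("  acceptance rate:", round(x$accept_rate, 3),
      "(tuned sigma_v2 =", signif(x$sigma_v2, 3), ")\n")
  invisible(x)
}
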