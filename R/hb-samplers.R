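#' Define a model for the generic Hamming ball samplers
#'
#' A model object is the plug-in contract between a statistical model and the
#' generic kernels: it supplies the (unnormalised) log joint density of the
#' latent state, and optionally a vectorised per-block weight function, a
#' conditional parameter update, and a parameter proposal for the marginal
#' Metropolis-Hastings scheme.
#'
#' @param log_joint `function(X, theta, data)` returning `log p(y, X, theta)`
#'   up to an additive constant; may return `-Inf` for zero-probability states.
#' @param block_log_weight Optional `function(idx, cand, X, theta, data)`
#'   where `idx` are the entry indices of a block and `cand` is a matrix with
#'   one candidate block value per row; must return one log weight per row,
#'   equal (up to a per-block additive constant) to `log_joint` evaluated at
#'   `X` with the block replaced by the candidate. When omitted, a loop over
#'   `log_joint` is used.
#' @param sample_theta Optional `function(X, theta, data)` drawing from the
#'   conditional `p(theta | X, y)` (required by the Gibbs kernel).
#' @param propose_theta Optional `function(theta, data)` drawing a proposal
#'   `theta'` (required by the marginal Metropolis-Hastings kernel).
#' @param log_proposal_theta Optional
#'   `function(theta_to, theta_from, data)` returning the log proposal
#'   density `log q(theta_to | theta_from)`; may be omitted for symmetric
#'   proposals.
#' @param factorized Logical; `TRUE` when, given `theta`, the joint weight
#'   factorises over the blocks of the partition (e.g. independent matrix
#'   columns). Factorised models admit exact joint latent draws inside the
#'   marginal schemes.
#' @param S Alphabet size of the latent entries (symbols `1..S`).
#' @return An object of class `hb_model`.
#' @export
hb_model <- function(log_joint, block_log_weight = NULL, sample_theta = NULL,
                     propose_theta = NULL, log_proposal_theta = NULL,
                     factorized = FALSE, S = 2L) {
  stopifnot(is.function(log_joint), S >= 2)
  if (is.null(block_log_weight)) {
    block_log_weight <- function(idx, cand, X, theta, data) {
      vapply(seq_len(nrow(cand)), function(r) {
        X[idx] <- cand[r, ]
        log_joint(X, theta, data)
      }, numeric(1))
    }
  }
  structure(list(log_joint = log_joint,
                 block_log_weight = block_log_weight,
                 sample_theta = sample_theta,
                 propose_theta = propose_theta,
                 log_proposal_theta = log_proposal_theta,
                 factorized = factorized,
                 S = as.integer(S)),
            class = "hb_model")
}

#' Split entry indices into blocks
#'
#' Either a fixed contiguous partition or a fresh uniformly-random partition
#' into blocks of size `K` (the final block may be shorter when `K` does not
#' divide the number of entries).
#'
#' @param D Number of latent entries.
#' @param K Block size.
#' @param random Draw a uniformly random permutation before chunking?
#' @return List of disjoint integer index vectors covering `1:D`.
#' @export
make_partition <- function(D, K, random = TRUE) {
  stopifnot(K >= 1, D >= 1)
  idx <- if (random) sample.int(D) else seq_len(D)
  split(idx, ceiling(seq_len(D) / K))
}

#' Resample the auxiliary state
#'
#' Draws each block of the auxiliary variable `U` independently from the
#' (possibly distance-weighted) Hamming ball around the corresponding block
#' of `X`. After the call every block satisfies the ball constraint
#' `d(u_i, x_i) <= m_i`.
#'
#' @param X Integer latent vector (symbols `1..S`).
#' @param partition List of index blocks.
#' @param m Ball radius; scalar or one radius per block.
#' @param S Alphabet size.
#' @param lambda Distance-decay weight of the auxiliary distribution
#'   (0 = uniform).
#' @return Integer vector `U` of the same shape as `X`.
#' @export
update_auxiliary <- function(X, partition, m, S = 2L, lambda = 0) {
  m <- rep_len(m, length(partition))
  U <- X
  for (i in seq_along(partition)) {
    idx <- partition[[i]]
    mi <- min(m[i], length(idx))
    if (mi > 0) U[idx] <- sample_ball(X[idx], mi, S = S, lambda = lambda)
  }
  U
}

#' Normalised weights over a restricted block slice
#'
#' Computes, for every candidate value of block `i` inside the Hamming ball
#' around the current auxiliary block `u_i`, the probability
#' `p(x_i | X_-i, theta, u_i, y)` proportional to the joint model weight
#' restricted to the ball. Weights are handled in log space with
#' max-subtraction before exponentiation.
#'
#' @param model An [hb_model()].
#' @param data Model data, passed through to the weight functions.
#' @param X Current latent vector.
#' @param idx Integer indices of the block being updated.
#' @param u_blk Current auxiliary block (the ball centre), length `length(idx)`.
#' @param theta Current model parameters.
#' @param m Ball radius for this block.
#' @param lambda Distance-decay weight; `> 0` multiplies each candidate's
#'   weight by `exp(-lambda * d(u_i, candidate))`, matching a non-uniform
#'   auxiliary distribution.
#' @return List with `candidates` (matrix, one per row), `log_weights`
#'   (unnormalised) and `prob` (normalised, summing to one).
#' @export
restricted_block_weights <- function(model, data, X, idx, u_blk, theta, m,
                                     lambda = 0) {
  cand <- enumerate_ball(u_blk, min(m, length(idx)), S = model$S)
  lw <- model$block_log_weight(idx, cand, X, theta, data)
  if (lambda > 0) {
    dists <- rowSums(cand != matrix(u_blk, nrow(cand), length(u_blk), byrow = TRUE))
    lw <- lw - lambda * dists
  }
  mx <- max(lw)
  if (!is.finite(mx)) {
    stop("restricted_block_weights(): every candidate in the slice has zero ",
         "probability (all log weights are -Inf)")
  }
  w <- exp(lw - mx)
  list(candidates = cand, log_weights = lw, prob = w / sum(w))
}

# Draw one candidate row index by inverse CDF on normalised weights.
.draw_categorical <- function(prob) {
  min(findInterval(stats::runif(1), cumsum(prob)) + 1L, length(prob))
}

#' One sweep of the block Hamming ball sampler
#'
#' Re-partitions the entries into random blocks of size `K` (unless a fixed
#' partition is supplied), then visits each block in sequence: draws the
#' auxiliary block uniformly from the ball around the current block, then
#' redraws the block from the restricted conditional over the ball around the
#' auxiliary block. Each block changes by at most `2m` entries per sweep, so
#' a sweep moves `X` by at most `2mP` entries.
#'
#' @inheritParams restricted_block_weights
#' @param K Block size used when re-partitioning.
#' @param partition Optional fixed partition; when `NULL` a fresh random
#'   partition into blocks of size `K` is drawn.
#' @return Updated latent vector, with attribute `n_evals` giving the number
#'   of candidate weight evaluations performed (`M * P` for equal blocks).
#' @export
block_hb_sweep <- function(model, data, X, theta, m, K,
                           lambda = 0, partition = NULL) {
  if (is.null(partition)) partition <- make_partition(length(X), K)
  n_evals <- 0L
  for (idx in partition) {
    mi <- min(m, length(idx))
    u <- sample_ball(X[idx], mi, S = model$S, lambda = lambda)
    rw <- restricted_block_weights(model, data, X, idx, u, theta, mi,
                                   lambda = lambda)
    n_evals <- n_evals + nrow(rw$candidates)
    X[idx] <- rw$candidates[.draw_categorical(rw$prob), ]
  }
  attr(X, "n_evals") <- n_evals
  X
}

#' One sweep of the standard block Gibbs sampler
#'
#' The `m = K` special case of [block_hb_sweep()]: the ball is the whole
#' block space, so each block is redrawn from its exact full conditional.
#' Exists so that small-block Gibbs baselines (e.g. `K = 1, 2, 3`) are
#' first-class comparators.
#'
#' @inheritParams block_hb_sweep
#' @export
block_gibbs_sweep <- function(model, data, X, theta, K, partition = NULL) {
  block_hb_sweep(model, data, X, theta, m = K, K = K, partition = partition)
}

#' One iteration of the auxiliary-variable Gibbs scheme
#'
#' Alternates `U <- p(U | X)`, `theta <- p(theta | X, y)`,
#' `X <- p(X | theta, U, y)`. The latent draw is exact (independent across
#' blocks) for factorised models; otherwise the blocks are scanned
#' sequentially, each from its restricted full conditional, which leaves the
#' same augmented target invariant.
#'
#' @inheritParams block_hb_sweep
#' @param partition Fixed partition of the entries.
#' @return List with elements `X`, `theta`, `U`.
#' @export
hb_gibbs_iteration <- function(model, data, X, theta, m, partition,
                               lambda = 0) {
  if (is.null(model$sample_theta)) {
    stop("hb_gibbs_iteration(): model does not provide sample_theta()")
  }
  U <- update_auxiliary(X, partition, m, S = model$S, lambda = lambda)
  theta <- model$sample_theta(X, theta, data)
  for (i in seq_along(partition)) {
    idx <- partition[[i]]
    rw <- restricted_block_weights(model, data, X, idx, U[idx], theta,
                                   m, lambda = lambda)
    X[idx] <- rw$candidates[.draw_categorical(rw$prob), ]
  }
  list(X = X, theta = theta, U = U)
}

# Sum over each block's ball of the (factorised) model weights:
# log ptilde(theta, U, y) up to a theta-independent constant.
.restricted_log_marginal_blocks <- function(model, data, X, U, theta, m,
                                            partition, lambda = 0) {
  total <- 0
  for (i in seq_along(partition)) {
    idx <- partition[[i]]
    cand <- enumerate_ball(U[idx], min(m, length(idx)), S = model$S)
    lw <- model$block_log_weight(idx, cand, X, theta, data)
    if (lambda > 0) {
      d <- rowSums(cand != matrix(U[idx], nrow(cand), length(idx), byrow = TRUE))
      lw <- lw - lambda * d
    }
    mx <- max(lw)
    total <- total + if (is.finite(mx)) mx + log(sum(exp(lw - mx))) else -Inf
  }
  total
}

#' One iteration of the marginal Metropolis-Hastings Hamming ball scheme
#'
#' Draws the auxiliary state, proposes `theta'`, and accepts with probability
#' `min(1, ptilde(theta', U, y) q(theta | theta') /
#' (ptilde(theta, U, y) q(theta' | theta)))`, where `ptilde` is the model
#' weight summed over the Hamming ball around `U` (a product of per-block
#' ball sums for factorised models). On acceptance the latent blocks are
#' redrawn jointly from the restricted conditional under `theta'`; on
#' rejection `(X, theta)` are kept.
#'
#' @inheritParams hb_gibbs_iteration
#' @return List with elements `X`, `theta`, `U`, `accepted`.
#' @export
hb_marginal_mh_iteration <- function(model, data, X, theta, m, partition,
                                     lambda = 0) {
  if (is.null(model$propose_theta)) {
    stop("hb_marginal_mh_iteration(): model does not provide propose_theta()")
  }
  if (!model$factorized && length(partition) > 1L) {
    stop("hb_marginal_mh_iteration(): the restricted marginal requires ",
         "per-block factorised weights (or a single block)")
  }
  U <- update_auxiliary(X, partition, m, S = model$S, lambda = lambda)
  theta_new <- model$propose_theta(theta, data)
  lm_cur <- .restricted_log_marginal_blocks(model, data, X, U, theta, m,
                                            partition, lambda)
  lm_new <- .restricted_log_marginal_blocks(model, data, X, U, theta_new, m,
                                            partition, lambda)
  if (!is.finite(lm_cur) && !is.finite(lm_new)) {
    stop("hb_marginal_mh_iteration(): restricted marginal is zero under both ",
         "the current and proposed parameters")
  }
  lr <- lm_new - lm_cur
  if (!is.null(model$log_proposal_theta)) {
    lr <- lr + model$log_proposal_theta(theta, theta_new, data) -
      model$log_proposal_theta(theta_new, theta, data)
  }
  accepted <- log(stats::runif(1)) < lr
  if (accepted) {
    theta <- theta_new
    for (i in seq_along(partition)) {
      idx <- partition[[i]]
      rw <- restricted_block_weights(model, data, X, idx, U[idx], theta,
                                     m, lambda = lambda)
      X[idx] <- rw$candidates[.draw_categorical(rw$prob), ]
    }
  }
  list(X = X, theta = theta, U = U, accepted = accepted)
}

#' One iteration with randomly drawn per-block radii
#'
#' Generalisation in which the radius vector `m = (m_1, ..., m_P)` is redrawn
#' each iteration from a user-supplied distribution before a sequential
#' auxiliary-variable update of each block. Blocks with `m_i = 0` are frozen.
#' The degenerate distribution that picks a single block `i`, sets `m_i` to
#' the block length and all other radii to zero reduces the scheme to a
#' single-block Gibbs sampler.
#'
#' @inheritParams hb_gibbs_iteration
#' @param rdist `function(P)` returning an integer vector of `P` per-block
#'   radii (each `0 <= m_i <=` block length).
#' @return List with elements `X`, `m` (the radii used).
#' @export
random_radius_iteration <- function(model, data, X, theta, rdist, partition,
                                    lambda = 0) {
  P <- length(partition)
  m_vec <- rep_len(rdist(P), P)
  for (i in seq_len(P)) {
    idx <- partition[[i]]
    mi <- min(m_vec[i], length(idx))
    if (mi == 0) next
    u <- sample_ball(X[idx], mi, S = model$S, lambda = lambda)
    rw <- restricted_block_weights(model, data, X, idx, u, theta, mi,
                                   lambda = lambda)
    X[idx] <- rw$candidates[.draw_categorical(rw$prob), ]
  }
  list(X = X, m = m_vec)
}

#' One iteration of Metropolized Shotgun Stochastic Search
#'
#' Pure Metropolis-Hastings comparator: proposes `X'` from the model weights
#' sliced to the Hamming ball around the current state and accepts with
#' probability `min(1, Z_m(X) / Z_m(X'))`, the ratio of sliced probability
#' volumes. Per iteration the state moves by at most `mP` entries -- half the
#' reach of the auxiliary-variable scheme at equal cost.
#'
#' @inheritParams hb_gibbs_iteration
#' @return List with elements `X`, `accepted`.
#' @export
msss_iteration <- function(model, data, X, theta, m, partition) {
  if (!model$factorized && length(partition) > 1L) {
    stop("msss_iteration(): requires per-block factorised weights ",
         "(or a single block)")
  }
  X_new <- X
  log_Z_cur <- 0
  for (i in seq_along(partition)) {
    idx <- partition[[i]]
    rw <- restricted_block_weights(model, data, X, idx, X[idx], theta, m)
    mx <- max(rw$log_weights)
    log_Z_cur <- log_Z_cur + mx + log(sum(exp(rw$log_weights - mx)))
    X_new[idx] <- rw$candidates[.draw_categorical(rw$prob), ]
  }
  log_Z_new <- 0
  for (i in seq_along(partition)) {
    idx <- partition[[i]]
    cand <- enumerate_ball(X_new[idx], min(m, length(idx)), S = model$S)
    lw <- model$block_log_weight(idx, cand, X_new, theta, data)
    mx <- max(lw)
    log_Z_new <- log_Z_new + mx + log(sum(exp(lw - mx)))
  }
  accepted <- log(stats::runif(1)) < (log_Z_cur - log_Z_new)
  list(X = if (accepted) X_new else X, accepted = accepted)
}

#' Run a sampler kernel for many iterations
#'
#' Seeds the RNG, runs burn-in followed by the sampling phase of the
#' requested kernel, and records the chain. Deterministic given
#' `(seed, config, data)`.
#'
#' @param model An [hb_model()].
#' @param data Model data.
#' @param config List of sampler settings: `kernel` (one of `"block_hb"`,
#'   `"block_gibbs"`, `"hb_gibbs"`, `"hb_marginal_mh"`, `"msss"`,
#'   `"random_radius"`), `D` (number of entries, required when `init` is
#'   absent), `m`, `K`, `lambda`, `iterations`, `burn_in`, `seed`, `thin`,
#'   `theta` (initial/fixed parameters), `init` (initial state; random
#'   uniform when omitted), `partition` (fixed partition for the
#'   non-repartitioning kernels), `repartition` (block kernels only; default
#'   `TRUE`), `update_theta` (block kernels: interleave `sample_theta`
#'   draws when the model provides them; default `TRUE`; set `FALSE` to
#'   sample at fixed parameters), `rdist` (radius distribution for
#'   `"random_radius"`).
#' @return An object of class `hb_chain`: list with integer matrix `x`
#'   (one recorded state per row), `theta` (list of recorded parameters),
#'   `accepted` (logical, M-H kernels), `config`, `seed`.
#' @export
run_chain <- function(model, data, config) {
  kernels <- c("block_hb", "block_gibbs", "hb_gibbs", "hb_marginal_mh",
               "msss", "random_radius")
  if (is.null(config$kernel) || !config$kernel %in% kernels) {
    stop("run_chain(): config$kernel must be one of ",
         paste(kernels, collapse = ", "))
  }
  if (is.null(config$iterations) || config$iterations < 1) {
    stop("run_chain(): config$iterations must be a positive integer")
  }
  kern <- config$kernel
  burn <- config$burn_in %||% 0L
  thin <- config$thin %||% 1L
  lambda <- config$lambda %||% 0
  if (!is.null(config$seed)) set.seed(config$seed)
  X <- config$init %||% sample.int(model$S, config$D, replace = TRUE)
  D <- length(X)
  theta <- config$theta
  K <- config$K %||% D
  partition <- config$partition %||% make_partition(D, K, random = FALSE)
  repartition <- config$repartition %||% TRUE
  if (kern %in% c("hb_gibbs", "hb_marginal_mh", "msss", "random_radius")) {
    repartition <- FALSE
  }
  # block kernels: interleave conditional theta draws when the model has
  # them, unless the run asks for theta to stay fixed
  upd_theta <- (config$update_theta %||% TRUE) &&
    !is.null(model$sample_theta)
  n_keep <- floor(config$iterations / thin)
  xs <- matrix(NA_integer_, n_keep, D)
  thetas <- vector("list", n_keep)
  acc <- logical(n_keep)
  kept <- 0L
  total <- burn + config$iterations
  for (t in seq_len(total)) {
    part_t <- if (repartition) make_partition(D, K) else partition
    accepted <- NA
    res <- switch(kern,
      block_hb = {
        if (upd_theta) theta <- model$sample_theta(X, theta, data)
        X <- block_hb_sweep(model, data, X, theta, config$m, K,
                            lambda = lambda, partition = part_t)
        NULL
      },
      block_gibbs = {
        if (upd_theta) theta <- model$sample_theta(X, theta, data)
        X <- block_gibbs_sweep(model, data, X, theta, K, partition = part_t)
        NULL
      },
      hb_gibbs = {
        r <- hb_gibbs_iteration(model, data, X, theta, config$m, part_t,
                                lambda = lambda)
        X <- r$X; theta <- r$theta
        NULL
      },
      hb_marginal_mh = {
        r <- hb_marginal_mh_iteration(model, data, X, theta, config$m, part_t,
                                      lambda = lambda)
        X <- r$X; theta <- r$theta; accepted <- r$accepted
        NULL
      },
      msss = {
        r <- msss_iteration(model, data, X, theta, config$m, part_t)
        X <- r$X; accepted <- r$accepted
        NULL
      },
      random_radius = {
        if (is.null(config$rdist)) {
          stop("run_chain(): random_radius kernel needs config$rdist")
        }
        r <- random_radius_iteration(model, data, X, theta, config$rdist,
                                     part_t, lambda = lambda)
        X <- r$X
        NULL
      })
    if (t > burn && (t - burn) %% thin == 0L) {
      kept <- kept + 1L
      xs[kept, ] <- X
      thetas[[kept]] <- theta
      acc[kept] <- isTRUE(accepted)
    }
  }
  structure(list(x = xs[seq_len(kept), , drop = FALSE],
                 theta = thetas[seq_len(kept)],
                 accepted = acc[seq_len(kept)],
                 config = config, seed = config$seed),
            class = "hb_chain")
}

#' @export
print.hb_chain <- function(x, ...) {
  cat("Hamming ball sampler chain\n")
  cat("  kernel:    ", x$config$kernel, "\n")
  cat("  recorded:  ", nrow(x$x), "states of dimension", ncol(x$x), "\n")
  if (any(!is.na(x$accepted)) && x$config$kernel %in% c("hb_marginal_mh", "msss")) {
    cat("  acceptance:", round(mean(x$accepted), 3), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
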