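test_that("restricted block weights normalise correctly", {
  # constant-weight model: uniform over the ball
  const_model <- hb_model(log_joint = function(X, theta, data) 0, S = 2L)
  rw <- restricted_block_weights(const_model, NULL, rep(1L, 4), 1:4,
                                 rep(1L, 4), NULL, m = 2)
  expect_equal(nrow(rw$candidates), ball_volume(2, 4))
  expect_equal(rw$prob, rep(1 / nrow(rw$candidates), nrow(rw$candidates)))
  expect_equal(sum(rw$prob), 1)

  # hand-normalised two-state slice: log weights (log 1, log 3)
  two_model <- hb_model(log_joint = function(X, theta, data) {
    if (X[1] == 1L) log(1) else log(3)
  }, S = 2L)
  rw2 <- restricted_block_weights(two_model, NULL, 1L, 1L, 1L, NULL, m = 1)
  expect_equal(rw2$prob, c(0.25, 0.75))

  # impossible slice errors
  dead <- hb_model(log_joint = function(X, theta, data) -Inf, S = 2L)
  expect_error(restricted_block_weights(dead, NULL, 1L, 1L, 1L, NULL, m = 1),
               "zero prob")
})

test_that("m = K restricted conditionals equal the exact full conditionals", {
  fx <- make_factorized_model(Kb = 4)
  set.seed(10)
  for (rep in 1:20) {
    X <- sample(1:2, fx$D, replace = TRUE)
    theta <- sample(fx$theta_grid, 1)
    i <- sample(1:2, 1)
    idx <- fx$partition[[i]]
    u <- sample(1:2, 4, replace = TRUE)  # arbitrary centre: ball is everything
    rw <- restricted_block_weights(fx$model, fx$data, X, idx, u, theta, m = 4)
    # exact conditional from the weight table
    st <- all_states(4)
    lw <- fx$model$block_log_weight(idx, st, X, theta, fx$data)
    exact <- exp(lw - max(lw)); exact <- exact / sum(exact)
    ord <- order(encode_states(rw$candidates))
    expect_lt(max(abs(rw$prob[ord] - exact[order(encode_states(st))])), 1e-12)
  }
})

test_that("simplified marginal M-H acceptance ratio equals the full ratio", {
  fx <- make_factorized_model(Kb = 3)
  m <- 2
  joint_weight <- function(X, theta) fx$model$log_joint(X, theta, fx$data)
  set.seed(11)
  for (rep in 1:50) {
    U <- sample(1:2, fx$D, replace = TRUE)
    theta <- sample(fx$theta_grid, 1)
    theta_new <- sample(fx$theta_grid, 1)
    # restricted normalisers and in-ball states under both parameter values
    ztil <- function(th) {
      tot <- 0
      for (i in 1:2) {
        idx <- fx$partition[[i]]
        cand <- enumerate_ball(U[idx], m)
        lw <- fx$model$block_log_weight(idx, cand, U, th, fx$data)
        tot <- tot + max(lw) + log(sum(exp(lw - max(lw))))
      }
      tot
    }
    draw_in_ball <- function() {
      X <- U
      for (i in 1:2) {
        idx <- fx$partition[[i]]
        cand <- enumerate_ball(U[idx], m)
        X[idx] <- cand[sample(nrow(cand), 1), ]
      }
      X
    }
    X <- draw_in_ball(); X_new <- draw_in_ball()
    cond <- function(X, th) joint_weight(X, th) - ztil(th)
    lhs <- (joint_weight(X_new, theta_new) - joint_weight(X, theta)) +
      (cond(X, theta) - cond(X_new, theta_new))
    rhs <- ztil(theta_new) - ztil(theta)
    expect_lt(abs(lhs - rhs), 1e-10)
  }
})

test_that("auxiliary update respects the ball constraint and its edge cases", {
  part <- split(1:12, rep(1:3, each = 4))
  set.seed(12)
  X <- sample(1:2, 12, replace = TRUE)
  expect_identical(update_auxiliary(X, part, m = 0), X)
  for (rep in 1:200) {
    U <- update_auxiliary(X, part, m = 2)
    for (idx in part) {
      expect_lte(hamming_distance(U[idx], X[idx]), 2)
    }
  }
  # m = K: the auxiliary block is uniform over the whole block space
  part1 <- list(1:3)
  draws <- replicate(8000, {
    encode_states(rbind(update_auxiliary(rep(1L, 3), part1, m = 3)))
  })
  chi <- suppressWarnings(chisq.test(table(factor(draws, levels = 1:8))))
  expect_gt(chi$p.value, 0.01)
})

test_that("per-sweep change bounds hold: 2mP for HB, mP for M-SSS", {
  fx <- make_factorized_model(Kb = 4)
  m <- 1
  P <- 2
  set.seed(13)
  X <- sample(1:2, fx$D, replace = TRUE)
  for (t in 1:400) {
    X2 <- block_hb_sweep(fx$model, fx$data, X, theta = 2, m = m, K = 4,
                         partition = fx$partition)
    expect_lte(hamming_distance(as.integer(X2), X), 2 * m * P)
    X <- as.integer(X2)
  }
  for (t in 1:400) {
    r <- msss_iteration(fx$model, fx$data, X, theta = 2, m = m,
                        partition = fx$partition)
    expect_lte(hamming_distance(r$X, X), m * P)
    X <- r$X
  }
})

test_that("per-sweep weight evaluations number M * P", {
  fx <- make_factorized_model(Kb = 4)
  set.seed(14)
  X <- sample(1:2, fx$D, replace = TRUE)
  X2 <- block_hb_sweep(fx$model, fx$data, X, theta = 1, m = 1, K = 4,
                       partition = fx$partition)
  expect_equal(attr(X2, "n_evals"), ball_volume(1, 4) * 2)
  X3 <- block_gibbs_sweep(fx$model, fx$data, X, theta = 1, K = 4,
                          partition = fx$partition)
  expect_equal(attr(X3, "n_evals"), 2^4 * 2)
})

test_that("degenerate random-radius distribution freezes all other blocks", {
  fx <- make_factorized_model(Kb = 4)
  set.seed(15)
  for (rep in 1:100) {
    X <- sample(1:2, fx$D, replace = TRUE)
    rdist <- function(P) c(4L, 0L)  # block 1 free, block 2 frozen
    r <- random_radius_iteration(fx$model, fx$data, X, theta = 3, rdist,
                                 fx$partition)
    expect_identical(r$X[fx$partition[[2]]], X[fx$partition[[2]]])
    expect_identical(r$m, c(4L, 0L))
  }
  # all radii zero: nothing moves
  r0 <- random_radius_iteration(fx$model, fx$data, rep(1L, fx$D), theta = 3,
                                function(P) c(0L, 0L), fx$partition)
  expect_identical(r0$X, rep(1L, fx$D))
})

test_that("identity proposals and flat slices are always accepted", {
  fx <- make_factorized_model(Kb = 3)
  ident <- fx$model
  ident$propose_theta <- function(theta, data) theta
  set.seed(16)
  X <- sample(1:2, fx$D, replace = TRUE)
  for (t in 1:30) {
    r <- hb_marginal_mh_iteration(ident, fx$data, X, theta = 2, m = 2,
                                  fx$partition)
    expect_true(r$accepted)
    X <- r$X
  }
  flat <- hb_model(log_joint = function(X, theta, data) 0,
                   factorized = TRUE, S = 2L)
  X <- rep(1L, 6)
  for (t in 1:30) {
    r <- msss_iteration(flat, NULL, X, NULL, m = 1,
                        split(1:6, rep(1:2, each = 3)))
    expect_true(r$accepted)
    X <- r$X
  }
})

test_that("zero-radius Hamming ball Gibbs leaves the latent state fixed", {
  fx <- make_factorized_model(Kb = 4)
  set.seed(17)
  X <- sample(1:2, fx$D, replace = TRUE)
  r <- hb_gibbs_iteration(fx$model, fx$data, X, theta = 1, m = 0,
                          fx$partition)
  expect_identical(r$X, X)
  expect_identical(r$U, X)
})

test_that("run_chain is deterministic, sized and validated", {
  fx <- make_factorized_model(Kb = 3)
  cfg <- list(kernel = "hb_gibbs", D = fx$D, m = 1, iterations = 50,
              burn_in = 10, seed = 99, partition = fx$partition, theta = 1)
  c1 <- run_chain(fx$model, fx$data, cfg)
  c2 <- run_chain(fx$model, fx$data, cfg)
  expect_identical(c1$x, c2$x)
  expect_identical(c1$theta, c2$theta)
  expect_equal(nrow(c1$x), 50)
  expect_error(run_chain(fx$model, fx$data, list(kernel = "nope",
                                                 iterations = 5)),
               "kernel")
  expect_error(run_chain(fx$model, fx$data, list(kernel = "hb_gibbs")),
               "iterations")
})
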