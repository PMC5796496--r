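test_that("log_marginal handles the empty model and basic structure", {
  set.seed(31)
  N <- 20; D <- 6
  Z <- matrix(rnorm(N * D), N, D)
  y <- rnorm(N)
  data <- list(y = y, Z = Z)
  hy <- regression_hyper(N)
  lm0 <- log_marginal(integer(D), data, hy)
  expect_equal(lm0,
               lgamma(hy$a_pi0) + lgamma(D + hy$b_pi0) -
                 0.5 * (2 * hy$a_sigma + N - 1) *
                 log(2 * hy$b_sigma + sum(y^2)))
})

test_that("log_marginal is exchangeable over identical columns and rank-safe", {
  sim <- gen_regression(seed = 32, N = 40, D_half = 25)
  data <- list(y = sim$y - mean(sim$y), Z = sim$Z)
  hy <- regression_hyper(40)
  x1 <- integer(50); x1[11] <- 1L
  x2 <- integer(50); x2[36] <- 1L
  expect_identical(log_marginal(x1, data, hy), log_marginal(x2, data, hy))
  # both members of a replica pair: singular Gram matrix, zero mass
  x12 <- integer(50); x12[c(11, 36)] <- 1L
  expect_identical(log_marginal(x12, data, hy), -Inf)
  # more active covariates than observations: also singular
  xbig <- integer(50); xbig[1:45] <- 1L
  expect_identical(log_marginal(xbig, data, hy), -Inf)
})

test_that("g-prior marginal matches a Monte Carlo integration oracle", {
  # At fixed sigma^2 the beta-integrated likelihood is
  #   -N/2 log(2 pi s2) - (Dx/2) log(1+g) - S(x) / (2 s2).
  # Verify the (1+g) shrinkage and the S(x) quadratic form by integrating
  # over beta ~ N(0, g s2 (Z'Z)^-1) with plain Monte Carlo.
  set.seed(33)
  N <- 6
  Z <- matrix(rnorm(N * 2), N, 2)
  y <- Z[, 1] * 0.8 + rnorm(N, 0, 0.6)
  g <- N
  s2 <- 0.5
  mc_log_marg <- function(act) {
    Zx <- Z[, act, drop = FALSE]
    Ginv <- solve(crossprod(Zx))
    L <- chol(g * s2 * Ginv)
    nmc <- 400000
    beta <- matrix(rnorm(nmc * length(act)), nmc) %*% L
    mu <- Zx %*% t(beta)                       # N x nmc fitted means
    ll <- colSums(dnorm(y, mu, sqrt(s2), log = TRUE))
    mx <- max(ll)
    mx + log(mean(exp(ll - mx)))
  }
  closed <- function(act) {
    Zx <- Z[, act, drop = FALSE]
    P <- Zx %*% solve(crossprod(Zx), t(Zx))
    S <- sum(y^2) - g / (1 + g) * as.numeric(t(y) %*% P %*% y)
    -N / 2 * log(2 * pi * s2) - length(act) / 2 * log(1 + g) - S / (2 * s2)
  }
  for (act in list(1L, 2L, c(1L, 2L))) {
    expect_lt(abs(mc_log_marg(act) - closed(act)), 0.05)
  }
})

test_that("compiled sweep agrees with the from-scratch R marginal", {
  sim <- gen_regression(seed = 34, N = 40, D_half = 25)
  data <- list(y = sim$y, Z = sim$Z)
  hy <- regression_hyper(40)
  ch <- regression_block_hb(data, hyper = hy, K = 5, m = 2,
                            iterations = 300, burn_in = 20, seed = 35)
  yc <- data$y - mean(data$y)
  dref <- list(y = yc, Z = data$Z)
  for (i in c(1, 100, 200, 300)) {
    x <- integer(50); x[ch$support[[i]]] <- 1L
    expect_equal(ch$logml[i], log_marginal(x, dref, hy), tolerance = 1e-8)
  }
})

test_that("replica inclusion probabilities are complementary", {
  sim <- gen_regression(seed = 36, N = 40, D_half = 25)
  ch <- regression_block_hb(list(y = sim$y, Z = sim$Z), K = 5, m = 1,
                            iterations = 4000, burn_in = 100, seed = 37)
  p <- inclusion_probabilities(ch)
  expect_gt(p[11] + p[36], 0.95)
  expect_lte(p[11] + p[36], 1 + 1e-12)
  # running version: cumulative mean of the indicators, last value = final
  run <- inclusion_probabilities(ch, indices = c(11, 36), running = TRUE)
  expect_equal(nrow(run), 4000)
  expect_equal(as.numeric(run[4000, ]), as.numeric(p[c(11, 36)]))
  ind <- vapply(ch$support, function(s) 11 %in% s, logical(1))
  expect_equal(run[, "11"], cumsum(ind) / seq_along(ind))
})

test_that("eval counts per sweep respect the ball volume bound", {
  sim <- gen_regression(seed = 38, N = 30, D_half = 20)
  ch <- regression_block_hb(list(y = sim$y, Z = sim$Z), K = 10, m = 1,
                            iterations = 50, burn_in = 0, seed = 39)
  expect_equal(ch$n_evals, 50 * 4 * ball_volume(1, 10))
})

test_that("correlation screening flags only correlated covariates", {
  set.seed(40)
  Z <- matrix(rnorm(600), 100, 6)
  y <- Z[, 3] + rnorm(100, 0, 0.4)
  flags <- correlation_screen(y, Z, threshold = 0.3)
  expect_true(flags[3])
  expect_lt(sum(flags[-3]), 3)
})
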