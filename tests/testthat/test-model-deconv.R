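test_that("vaf reproduces the reference frequency vector and edge cases", {
  tr <- tumor_fixture()
  expect_equal(vaf(tr$theta0, tr$X0, 0),
               c(0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.15, 0.15, 0.15))
  # p = 0 maps to e; p = 0.5 is a fixed point for any error rate
  X <- rbind(c(0L, 1L), c(0L, 1L))
  expect_equal(as.numeric(vaf(c(0.5, 0.5), X, 0.03)), c(0.03, 0.5))
})

test_that("binomial log likelihood matches longhand factorial computation", {
  r <- 3L; d <- 10L; phi <- 0.37
  longhand <- lchoose(d, r) + r * log(phi) + (d - r) * log(1 - phi)
  expect_equal(deconv_log_lik(r, d, phi), longhand)
  # additivity across variants
  expect_equal(deconv_log_lik(c(3L, 5L), c(10L, 12L), c(0.37, 0.4)),
               deconv_log_lik(3L, 10L, 0.37) + deconv_log_lik(5L, 12L, 0.4))
  # impossible outcome under a degenerate frequency
  expect_identical(deconv_log_lik(1L, 2L, 0), -Inf)
})

test_that("log-gamma prior density is correctly normalised", {
  # per-component density at v = 0 with shape 1 is exp(-1)
  expect_equal(exp(log_prior_v(0, alpha = 1, K = 1)), exp(-1))
  # integrates to one for shapes 1 and 0.5
  for (shape in c(1, 0.5)) {
    total <- integrate(function(v) {
      vapply(v, function(vi) exp(log_prior_v(vi, alpha = shape, K = 1)),
             numeric(1))
    }, -40, 15, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # matches direct transformation of Gamma draws
  set.seed(51)
  v <- log(rgamma(2e5, 0.5, 1))
  expect_equal(mean(v < -1),
               integrate(function(z) {
                 vapply(z, function(vi) exp(log_prior_v(vi, 0.5, 1)), 0)
               }, -40, -1)$value,
               tolerance = 0.01)
})

test_that("restricted marginal with m = K equals exhaustive joint summation", {
  # independent oracle: sum p(y | X, theta) p(X | f) over ALL 2^(K*N) joint
  # genotype matrices, not using the per-column factorisation
  K <- 3L; N <- 2L
  counts <- data.frame(variant_id = c("a", "b"), sample_id = "s",
                       variant_reads = c(11L, 4L), depth = c(30L, 25L))
  hy <- deconv_hyper(K = K, m = K, e = 0.01)
  set.seed(52)
  v <- log(rgamma(K, 1, 1))
  f <- c(0.3, 0.6)
  U <- matrix(rbinom(K * N, 1, 0.5), K, N)
  theta <- exp(v) / sum(exp(v))
  cols <- as.matrix(expand.grid(rep(list(0:1), K)))
  joint <- 0
  total <- 0
  for (i1 in seq_len(nrow(cols))) {
    for (i2 in seq_len(nrow(cols))) {
      X <- cbind(cols[i1, ], cols[i2, ])
      phi <- vaf(theta, X, hy$e)
      lik <- exp(deconv_log_lik(counts$variant_reads, counts$depth, phi))
      pX <- prod(f^colSums(X) * (1 - f)^(K - colSums(X)))
      total <- total + lik * pX
    }
  }
  oracle <- log(total) + log_prior_v(v, hy$alpha, K)
  expect_equal(restricted_log_marginal(v, U, counts, f, hy), oracle,
               tolerance = 1e-10)
})

test_that("restricted marginal with m = 0 reduces to the single term at U", {
  K <- 3L
  counts <- data.frame(variant_id = c("a", "b"), sample_id = "s",
                       variant_reads = c(11L, 4L), depth = c(30L, 25L))
  hy <- deconv_hyper(K = K, m = 0, e = 0.01)
  set.seed(53)
  v <- log(rgamma(K, 1, 1))
  f <- c(0.3, 0.6)
  U <- matrix(rbinom(K * 2, 1, 0.5), K, 2)
  theta <- exp(v) / sum(exp(v))
  phi <- vaf(theta, U, hy$e)
  direct <- deconv_log_lik(counts$variant_reads, counts$depth, phi) +
    sum(colSums(U) * log(f) + (K - colSums(U)) * log(1 - f)) +
    log_prior_v(v, hy$alpha, K)
  expect_equal(restricted_log_marginal(v, U, counts, f, hy), direct,
               tolerance = 1e-10)
})

test_that("duplicated samples double the likelihood inside the ball sums", {
  K <- 3L
  counts1 <- data.frame(variant_id = c("a", "b"), sample_id = "s1",
                        variant_reads = c(11L, 4L), depth = c(30L, 25L))
  counts2 <- rbind(counts1,
                   transform(counts1, sample_id = "s2"))
  hy <- deconv_hyper(K = K, m = K, e = 0.01)
  set.seed(54)
  v <- log(rgamma(K, 1, 1))
  f <- c(0.3, 0.6)
  U <- matrix(rbinom(K * 2, 1, 0.5), K, 2)
  lm2 <- restricted_log_marginal(cbind(v, v), U, counts2, f, hy)
  # oracle: per-column sums with the likelihood term squared
  theta <- exp(v) / sum(exp(v))
  cols <- as.matrix(expand.grid(rep(list(0:1), K)))
  tot <- 0
  for (i in 1:2) {
    li <- apply(cols, 1, function(xc) {
      phi <- vaf(theta, cbind(xc), hy$e)
      2 * deconv_log_lik(counts1$variant_reads[i], counts1$depth[i], phi) +
        sum(xc) * log(f[i]) + (K - sum(xc)) * log(1 - f[i])
    })
    tot <- tot + max(li) + log(sum(exp(li - max(li))))
  }
  expect_equal(lm2, tot + 2 * log_prior_v(v, hy$alpha, K), tolerance = 1e-10)
})

test_that("frequency Gibbs update draws from the conjugate Beta", {
  hy <- deconv_hyper(K = 8)
  X <- cbind(rep(1L, 8), rep(0L, 8), c(rep(1L, 3), rep(0L, 5)))
  set.seed(55)
  f <- gibbs_f_update(X, hy)
  set.seed(55)
  expected <- rbeta(3, c(8.5, 0.5, 3.5), c(0.5, 8.5, 5.5))
  expect_identical(f, expected)
})

test_that("proposal tuning moves towards the band and clips hard", {
  expect_lt(tune_proposal(1, 0.05), 1)
  expect_gt(tune_proposal(1, 0.6), 1)
  expect_identical(tune_proposal(1, 0.25), 1)
  expect_identical(tune_proposal(8, 0.9), 10)
  expect_identical(tune_proposal(0.015, 0.01), 0.01)
})

test_that("joint weight/genotype update only moves the state on acceptance", {
  tum <- tumor_fixture()
  hy <- deconv_hyper(K = 4, m = 2)
  set.seed(56)
  v <- log(rgamma(4, 0.25, 1))
  X <- matrix(rbinom(36, 1, 0.5), 4, 9)
  f <- rep(0.5, 9)
  U <- X
  n_acc <- 0
  for (rep in 1:40) {
    res <- mh_theta_X_update(v, X, f, U, tum$counts, hy, sigma_v2 = 1)
    if (res$accepted) {
      n_acc <- n_acc + 1
      v <- as.numeric(res$v)
      X <- res$X
    } else {
      expect_identical(as.numeric(res$v), as.numeric(v))
      expect_identical(res$X, X)
    }
  }
  expect_gt(n_acc, 0)
})

test_that("posterior mean of max(theta) matches an importance-sampling oracle", {
  # tiny instance with the fully marginalised sampler (m = K)
  K <- 2L
  counts <- data.frame(variant_id = c("a", "b"), sample_id = "s",
                       variant_reads = c(12L, 20L), depth = c(30L, 30L))
  hy <- deconv_hyper(K = K, m = K, alpha = 1, e = 0.01)
  fit <- deconv_hb(counts, hy, iterations = 30000, burn_in = 5000,
                   tune_iters = 1000, seed = 57)
  # oracle: importance sampling from the prior over (gamma, f)
  set.seed(58)
  nis <- 300000
  g1 <- rgamma(nis, 0.5, 1); g2 <- rgamma(nis, 0.5, 1)
  th <- cbind(g1, g2) / (g1 + g2)
  f1 <- rbeta(nis, 0.5, 0.5); f2 <- rbeta(nis, 0.5, 0.5)
  cols <- as.matrix(expand.grid(0:1, 0:1))  # column states over K = 2
  lik_col <- function(r, d, fv) {
    tot <- 0
    for (s in seq_len(nrow(cols))) {
      p <- 0.5 * (th %*% cols[s, ])
      phi <- (1 - hy$e) * p + hy$e * (1 - p)
      pX <- fv^sum(cols[s, ]) * (1 - fv)^(K - sum(cols[s, ]))
      tot <- tot + dbinom(r, d, phi) * pX
    }
    tot
  }
  w <- lik_col(12L, 30L, f1) * lik_col(20L, 30L, f2)
  oracle <- sum(w * pmax(th[, 1], th[, 2])) / sum(w)
  expect_lt(abs(mean(fit$max_theta) - oracle), 0.03)
})

test_that("fresh forward simulations are recovered within binomial error", {
  sim <- gen_tumor(seed = 59, fresh = TRUE)
  fit <- deconv_hb(sim$counts, deconv_hyper(m = 4), iterations = 6000,
                   burn_in = 4000, seed = 60)
  phi0 <- (1 - 0.01) * sim$p0 + 0.01 * (1 - sim$p0)
  expect_lt(max(abs(fit$phi_mean - phi0)), 0.04)
  # acceptance rate lands in a plausible tuned range
  expect_gt(fit$accept_rate, 0.05)
  expect_lt(fit$accept_rate, 0.6)
})

test_that("reported summaries are invariant to component relabelling", {
  set.seed(61)
  theta <- c(0.2, 0.5, 0.3)
  X <- matrix(rbinom(18, 1, 0.5), 3, 6)
  perm <- c(3, 1, 2)
  expect_equal(vaf(theta[perm], X[perm, ], 0.01), vaf(theta, X, 0.01))
  expect_equal(max(theta[perm]), max(theta))
})

test_that("multi-sample fits share genotypes and expose residuals", {
  sim <- gen_multisample_tumor(S = 4, seed = 62, n_variants = 6, K0 = 3)
  hy <- deconv_hyper(K = 4, m = 2)
  fit <- deconv_hb(sim$counts, hy, iterations = 800, burn_in = 800,
                   tune_iters = 400, seed = 63)
  expect_equal(dim(fit$phi_mean), c(6, 4))
  expect_equal(dim(fit$max_theta), c(800, 4))
  res <- residual_matrix(fit$r, fit$d, fit$phi_mean)
  expect_equal(dim(res), c(6, 4))
  expect_true(all(is.finite(res)))
  expect_lt(max(abs(res)), 0.5)
})
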