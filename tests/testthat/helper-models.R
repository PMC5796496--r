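# Shared fixtures: tiny models with exhaustively enumerable posteriors,
# used to check every sampler kernel against brute force.

# All S^D states as rows (binary counting order in the first column fastest).
all_states <- function(D, S = 2) {
  st <- as.matrix(expand.grid(rep(list(seq_len(S)), D)))
  dimnames(st) <- NULL
  storage.mode(st) <- "integer"
  st
}

encode_states <- function(xmat, S = 2) {
  D <- ncol(xmat)
  as.integer((xmat - 1L) %*% S^(0:(D - 1))) + 1L
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Exact posterior over all states of an hb_model at fixed theta.
brute_posterior <- function(model, data, D, theta = NULL, S = 2) {
  st <- all_states(D, S)
  lw <- apply(st, 1, function(x) model$log_joint(as.integer(x), theta, data))
  lw[!is.finite(lw)] <- -Inf
  w <- exp(lw - max(lw))
  w / sum(w)
}

empirical_dist <- function(xmat, nstates, S = 2) {
  tabulate(encode_states(xmat, S), nstates) / nrow(xmat)
}

# Factorised tiny model: P = 2 binary blocks of size Kb; per-block log
# weight B_i[state] + theta * C_i[state], theta on an integer grid.
# Tables drawn once from a fixed seed so tests are reproducible.
make_factorized_model <- function(Kb = 4, theta_grid = 1:5, seed = 42,
                                  scale = 1) {
  set.seed(seed)
  nstate <- 2^Kb
  tabB <- list(rnorm(nstate, 0, scale), rnorm(nstate, 0, scale))
  tabC <- list(rnorm(nstate, 0, 0.3 * scale), rnorm(nstate, 0, 0.3 * scale))
  block_of <- rep(1:2, each = Kb)
  data <- list(tabB = tabB, tabC = tabC, block_of = block_of, Kb = Kb)
  bidx <- function(cand) as.integer((cand - 1L) %*% 2^(0:(ncol(cand) - 1))) + 1L
  blw <- function(idx, cand, X, theta, data) {
    i <- data$block_of[idx[1]]
    s <- bidx(cand)
    th <- if (is.null(theta)) 0 else theta
    data$tabB[[i]][s] + th * data$tabC[[i]][s]
  }
  lj <- function(X, theta, data) {
    th <- if (is.null(theta)) 0 else theta
    s1 <- sum((X[1:data$Kb] - 1L) * 2^(0:(data$Kb - 1))) + 1L
    s2 <- sum((X[(data$Kb + 1):(2 * data$Kb)] - 1L) * 2^(0:(data$Kb - 1))) + 1L
    data$tabB[[1]][s1] + th * data$tabC[[1]][s1] +
      data$tabB[[2]][s2] + th * data$tabC[[2]][s2]
  }
  sample_theta <- function(X, theta, data) {
    lw <- vapply(theta_grid, function(th) lj(X, th, data), numeric(1))
    w <- exp(lw - max(lw))
    theta_grid[min(findInterval(runif(1), cumsum(w / sum(w))) + 1L,
                   length(theta_grid))]
  }
  propose_theta <- function(theta, data) sample(theta_grid, 1L)
  model <- hb_model(log_joint = lj, block_log_weight = blw,
                    sample_theta = sample_theta,
                    propose_theta = propose_theta,
                    factorized = TRUE, S = 2L)
  # exact joint posterior over (theta, X)
  st <- all_states(2 * Kb)
  joint <- sapply(theta_grid, function(th) {
    apply(st, 1, function(x) lj(as.integer(x), th, data))
  })
  jw <- exp(joint - max(joint))
  list(model = model, data = data, theta_grid = theta_grid,
       D = 2 * Kb, partition = split(seq_len(2 * Kb), block_of),
       joint_post = jw / sum(jw),   # nstates x n_theta
       x_post = rowSums(jw) / sum(jw))
}

# Small toy-regression instance (non-factorised): D covariates, replicas in
# the second half, enumerable posterior.
make_small_toy <- function(D = 12, n = 40, sigma2 = 1, seed = 7) {
  gen_toy(sigma2, seed = seed, n = n, D = D)
}

# Tumor counts fixture
tumor_fixture <- function() gen_tumor()
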