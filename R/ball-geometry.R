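#' Hamming distance between two block states
#'
#' Counts the positions at which two equal-length categorical vectors differ.
#' This is the metric that defines the neighbourhoods ("Hamming balls") used
#' by every sampler in the package.
#'
#' @param a,b Integer (or otherwise comparable) vectors of equal length.
#' @return Non-negative integer count of differing positions.
#' @examples
#' hamming_distance(c(1L, 2L, 1L, 2L), c(1L, 1L, 1L, 1L))  # 2
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("hamming_distance(): states have different lengths (",
         length(a), " vs ", length(b), ")")
  }
  sum(a != b)
}

#' Volume of a Hamming ball
#'
#' Number of states of an S-ary block of length `K` lying within Hamming
#' distance `m` of an arbitrary centre, \eqn{M = \sum_{j=0}^{m} (S-1)^j
#' \binom{K}{j}}. The volume does not depend on the centre, which is what
#' makes the auxiliary uniform distribution over the ball normalisable in
#' closed form. With `lambda > 0` the distance-weighted volume
#' \eqn{M_\lambda = \sum_j e^{-\lambda j} (S-1)^j \binom{K}{j}} is returned,
#' the normaliser of the auxiliary distribution that concentrates mass
#' towards the centre.
#'
#' @param m Ball radius, `0 <= m <= K`.
#' @param K Block length.
#' @param S Alphabet size (`S >= 2`).
#' @param lambda Non-negative distance-decay weight; `0` gives the uniform
#'   ball and an integer volume.
#' @return The (possibly weighted) ball volume.
#' @examples
#' ball_volume(1, 10)        # 11
#' ball_volume(3, 10)        # 176
#' ball_volume(8, 8, S = 2)  # 2^8
#' @export
ball_volume <- function(m, K, S = 2, lambda = 0) {
  stopifnot(m >= 0, K >= 1, m <= K, S >= 2, lambda >= 0)
  j <- 0:m
  if (lambda == 0) {
    sum((S - 1)^j * choose(K, j))
  } else {
    sum(exp(-lambda * j + j * log(S - 1) + lchoose(K, j)))
  }
}

#' Enumerate all states in a Hamming ball
#'
#' Returns every length-`K` state over the alphabet `1..S` whose Hamming
#' distance from `center` is at most `m`, each exactly once. Enumeration
#' order is deterministic: distance class `j = 0..m`, position subsets in
#' lexicographic order, substituted symbols in increasing order.
#'
#' @param center Integer vector with entries in `1..S`.
#' @param m Ball radius, `0 <= m <= length(center)`.
#' @param S Alphabet size.
#' @return Integer matrix with one state per row; `ball_volume(m, K, S)` rows.
#' @examples
#' enumerate_ball(c(1L, 1L), 1, S = 2)
#' @export
enumerate_ball <- function(center, m, S = 2) {
  K <- length(center)
  if (m < 0 || m > K) stop("enumerate_ball(): radius m must satisfy 0 <= m <= K")
  stopifnot(all(center >= 1), all(center <= S))
  if (S == 2) {
    # binary fast path: cached flip-position table, single substitution each
    fm <- .flip_matrix(K, m)
    cand <- matrix(center, nrow(fm), K, byrow = TRUE)
    cand[fm] <- 3L - cand[fm]
    return(cand)
  }
  out <- vector("list", m + 1L)
  out[[1L]] <- matrix(center, nrow = 1L)
  if (m >= 1L) {
    for (j in seq_len(m)) {
      pos_sets <- utils::combn(K, j)
      rows <- vector("list", ncol(pos_sets))
      # (S-1)^j symbol substitutions per position subset, in symbol order
      for (cidx in seq_len(ncol(pos_sets))) {
        pos <- pos_sets[, cidx]
        alts <- lapply(pos, function(p) setdiff(seq_len(S), center[p]))
        grid <- as.matrix(expand.grid(rev(alts)))[, rev(seq_len(j)), drop = FALSE]
        blk <- matrix(center, nrow = nrow(grid), ncol = K, byrow = TRUE)
        blk[, pos] <- grid
        rows[[cidx]] <- blk
      }
      out[[j + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  storage.mode(res) <- "integer"
  res
}

# Cache of flip-position tables: rows enumerate all position subsets of
# size <= m in (distance, lexicographic) order.
.ball_cache <- new.env(parent = emptyenv())

.flip_matrix <- function(K, m) {
  key <- paste(K, m, sep = ":")
  fm <- .ball_cache[[key]]
  if (is.null(fm)) {
    rows <- vector("list", ball_volume(m, K, S = 2))
    rows[[1L]] <- rep(FALSE, K)
    n <- 1L
    if (m >= 1L) {
      for (j in seq_len(m)) {
        cs <- utils::combn(K, j)
        for (cc in seq_len(ncol(cs))) {
          r <- rep(FALSE, K)
          r[cs[, cc]] <- TRUE
          n <- n + 1L
          rows[[n]] <- r
        }
      }
    }
    fm <- do.call(rbind, rows)
    .ball_cache[[key]] <- fm
  }
  fm
}

#' Draw a state uniformly (or distance-weighted) from a Hamming ball
#'
#' Samples a state within Hamming distance `m` of `center` without
#' materialising the ball: first the distance class `j` with probability
#' proportional to \eqn{e^{-\lambda j} (S-1)^j \binom{K}{j}}, then a uniform
#' `j`-subset of positions, then uniform alternative symbols. For
#' `lambda = 0` every ball member is equally likely; for `lambda > 0` the
#' probability of a state at distance `d` is proportional to
#' \eqn{e^{-\lambda d}}.
#'
#' @inheritParams enumerate_ball
#' @param lambda Non-negative distance-decay weight (0 = uniform).
#' @return An integer vector: one sampled state.
#' @export
sample_ball <- function(center, m, S = 2, lambda = 0) {
  K <- length(center)
  if (m < 0 || m > K) stop("sample_ball(): radius m must satisfy 0 <= m <= K")
  if (m == 0L) return(center)
  j <- 0:m
  lw <- -lambda * j + j * log(S - 1) + lchoose(K, j)
  w <- exp(lw - max(lw))
  d <- sample.int(m + 1L, 1L, prob = w) - 1L
  if (d == 0L) return(center)
  pos <- if (K == 1L) 1L else sample.int(K, d)
  out <- center
  for (p in pos) {
    alt <- setdiff(seq_len(S), center[p])
    out[p] <- if (length(alt) == 1L) alt else alt[sample.int(length(alt), 1L)]
  }
  out
}

#' Ball membership test
#'
#' `TRUE` iff `hamming_distance(u, center) <= m`. Symmetric in its two state
#' arguments, which is the property that lets the auxiliary construction be
#' inverted: `u` is in the ball around `x` exactly when `x` is in the ball
#' around `u`.
#'
#' @param u,center Equal-length state vectors.
#' @param m Ball radius.
#' @return Logical scalar.
#' @export
in_ball <- function(u, center, m) {
  hamming_distance(u, center) <= m
}
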