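#' Integrated autocorrelation time
#'
#' Estimates \eqn{\tau = 1 + 2 \sum_k \rho_k} by the initial-positive-sequence
#' rule: autocorrelations are summed in adjacent pairs and the sum is
#' truncated at the first non-positive pair (Geyer's initial positive
#' sequence estimator). The estimate is clipped below at 1. A constant
#' series has no information content; its IAT is defined as the series
#' length (ESS of 1) with a warning.
#'
#' @param x Numeric series (e.g. a parameter trace), length >= 100.
#' @return The estimated integrated autocorrelation time (>= 1), with the
#'   effective sample size `length(x) / iat` attached as attribute `"ess"`.
#' @seealso [ess()]
#' @export
iat <- function(x) {
  n <- length(x)
  if (n < 100) stop("iat(): series too short (need length >= 100)")
  if (stats::var(x) == 0) {
    warning("iat(): constant series; IAT set to the series length")
    out <- n
    attr(out, "ess") <- 1
    return(out)
  }
  lag_max <- min(n - 1, 2000L)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  # pair sums Gamma_k = rho_{2k} + rho_{2k+1}; keep while positive
  npair <- floor(length(rho) / 2)
  tau <- 1
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g <= 0) break
    tau <- tau + 2 * g
  }
  out <- max(1, tau)
  attr(out, "ess") <- n / out
  out
}

#' Effective sample size
#'
#' `length(x)` divided by the integrated autocorrelation time.
#'
#' @inheritParams iat
#' @return Effective sample size (at most `length(x)`).
#' @export
ess <- function(x) {
  as.numeric(attr(iat(x), "ess"))
}

#' Count switches between posterior modes
#'
#' Given a per-iteration mode occupancy sequence (labels with `NA` marking
#' iterations that belong to no mode), counts the transitions between
#' distinct consecutive occupancies, ignoring unassigned iterations.
#' Alternatively, a numeric series plus a list of disjoint predicate
#' functions can be supplied and the occupancy sequence is derived.
#'
#' @param series Mode labels (character/factor/integer, `NA` = no mode), or
#'   a numeric series when `modes` is given.
#' @param modes Optional named list of predicate functions, each mapping the
#'   series to a logical vector; predicates must be disjoint.
#' @return Non-negative integer switch count.
#' @examples
#' mode_switches(c("A", "B", "A", "B"))  # 3
#' @export
mode_switches <- function(series, modes = NULL) {
  if (!is.null(modes)) {
    hits <- vapply(modes, function(f) f(series), logical(length(series)))
    if (any(rowSums(hits) > 1)) {
      stop("mode_switches(): mode predicates are not disjoint")
    }
    lab <- rep(NA_character_, length(series))
    for (nm in colnames(hits)) lab[hits[, nm]] <- nm
    series <- lab
  }
  occ <- series[!is.na(series)]
  if (length(occ) < 2) return(0L)
  sum(occ[-1] != occ[-length(occ)])
}

#' Overall sampling efficiency
#'
#' Ratio of mode switches (a proxy for effective independent samples in a
#' multimodal target) to wall-clock time. Hardware dependent: meaningful
#' only for ranking schemes run on the same machine, never as an absolute
#' quantity.
#'
#' @param switches Number of mode switches observed.
#' @param time Wall time spent, in any fixed unit (> 0).
#' @return `switches / time`.
#' @export
overall_efficiency <- function(switches, time) {
  stopifnot(time > 0, switches >= 0)
  switches / time
}

#' Model-fit residual matrix
#'
#' Elementwise difference between the observed variant allele frequencies
#' `r/d` and the posterior mean fitted frequencies, per variant and sample.
#' Cells with zero depth are undefined and returned as `NA`.
#'
#' @param r Matrix (or vector) of variant-read counts.
#' @param d Matrix (or vector) of total depths, same shape as `r`.
#' @param phi_mean Posterior mean variant allele frequencies, same shape.
#' @return Matrix of residuals `r/d - phi_mean` with `NA` where `d == 0`.
#' @export
residual_matrix <- function(r, d, phi_mean) {
  stopifnot(length(r) == length(d), length(r) == length(phi_mean))
  res <- r / d - phi_mean
  res[d == 0] <- NA_real_
  res
}

#' Locate modes of a scalar trace by density segmentation
#'
#' Finds the local maxima of a kernel density estimate of the trace,
#' segments the trace at the valleys between retained peaks, and reports
#' each mode's location (peak position) and mass (fraction of iterations in
#' its segment). Peaks with mass below `min_mass` are merged into their
#' neighbour.
#'
#' @param x Numeric trace.
#' @param min_mass Minimum fraction of iterations for a reported mode.
#' @param bw Bandwidth argument passed to [stats::density()].
#' @return Data frame with columns `location`, `mass`, `lower`, `upper`
#'   (segment boundaries), ordered by location.
#' @export
trace_modes <- function(x, min_mass = 0.02, bw = "nrd0") {
  den <- stats::density(x, bw = bw)
  y <- den$y
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(pk) == 0) pk <- which.max(y)
  repeat {
    # segment at minima between consecutive peaks
    cuts <- vapply(seq_len(length(pk) - 1L), function(i) {
      seg <- pk[i]:pk[i + 1L]
      den$x[seg[which.min(y[seg])]]
    }, numeric(1))
    bounds <- c(-Inf, cuts, Inf)
    mass <- vapply(seq_along(pk), function(i) {
      mean(x >= bounds[i] & x < bounds[i + 1L])
    }, numeric(1))
    if (all(mass >= min_mass) || length(pk) == 1L) break
    pk <- pk[-which.min(mass)]
  }
  data.frame(location = den$x[pk], mass = mass,
             lower = bounds[seq_along(pk)], upper = bounds[seq_along(pk) + 1L])
}
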