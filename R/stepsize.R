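#' Stepsize rules for the stochastic reconstruction loop
#'
#' `vanishing_stepsize` implements the decaying rule
#' `tau(k) = tau0 / (1 + eta k / n)`, which satisfies the usual
#' divergent-sum / convergent-square-sum conditions for `eta > 0` and
#' reduces to a constant stepsize at `eta = 0`.
#'
#' `bb_short_stepsize` is the short-form Barzilai-Borwein ratio
#' `tau = (p'q) / (q'q)` with `p = x(k) - x(k-1)` and
#' `q = grad(k) - grad(k-1)` (plain Euclidean inner products). For
#' stochastic variance-reduced loops the differences are anchored at
#' consecutive full-gradient snapshots. A non-positive or undefined ratio
#' returns `NA`, signalling the caller to retain the previous stepsize.
#'
#' `alg1_stepsize` is the fixed piecewise schedule used by the ALG1
#' preset: 3 for `k < 10`, 2 for `10 <= k < 100`, 1.5 for
#' `100 <= k < 200`, 1 for `200 <= k < 300`, and 0.5 from `k = 300` on
#' (`k` counts subset updates from 0).
#'
#' `capped_bb_stepsize` is the ALG2/ALG3 schedule: the current BB value
#' capped at 3 for `k < 10`, at 2.2 for `10 <= k < 2n`, and at 1 for
#' `k >= 2n`. Before the first BB value is available the cap itself is
#' used (i.e. `bb_tau` is treated as `+Inf`).
#'
#' @param k 0-based update counter.
#' @param tau0 positive initial stepsize.
#' @param eta non-negative decay parameter.
#' @param n number of subsets per epoch.
#' @param p,q image arrays (iterate and gradient differences).
#' @param bb_tau latest short-form BB value, or `NULL`/`NA` if none has
#'   been computed yet.
#' @return a positive stepsize (or `NA` from `bb_short_stepsize` when no
#'   update is possible).
#' @export
vanishing_stepsize <- function(k, tau0, eta, n) {
  if (tau0 <= 0) stop("tau0 must be positive")
  if (eta < 0) stop("eta must be non-negative")
  if (n < 1) stop("n must be >= 1")
  if (any(k < 0)) stop("k must be >= 0")
  tau0 / (1 + eta * k / n)
}

#' @rdname vanishing_stepsize
#' @export
bb_short_stepsize <- function(p, q) {
  qq <- sum(q * q)
  if (qq == 0) return(NA_real_)
  tau <- sum(p * q) / qq
  if (!is.finite(tau) || tau <= 0) return(NA_real_)
  tau
}

#' @rdname vanishing_stepsize
#' @export
alg1_stepsize <- function(k) {
  if (any(k < 0)) stop("k must be >= 0")
  ifelse(k < 10, 3,
         ifelse(k < 100, 2,
                ifelse(k < 200, 1.5,
                       ifelse(k < 300, 1, 0.5))))
}

#' @rdname vanishing_stepsize
#' @export
capped_bb_stepsize <- function(k, n, bb_tau = NULL) {
  if (any(k < 0)) stop("k must be >= 0")
  if (n < 1) stop("n must be >= 1")
  if (is.null(bb_tau) || is.na(bb_tau)) bb_tau <- Inf
  cap <- ifelse(k < 10, 3, ifelse(k < 2 * n, 2.2, 1))
  pmin(bb_tau, cap)
}
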