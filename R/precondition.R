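#' Diagonal preconditioners for the stochastic reconstruction loop
#'
#' `mlem_preconditioner` is the classic EM-derived diagonal
#' `D_MLEM(x) = (x + delta) / (A' 1)`; a small `delta > 0` keeps every
#' entry strictly positive even where the current image is zero.
#'
#' `prior_preconditioner` is the reciprocal of the diagonal Hessian of the
#' scaled prior, `D_betaS(x) = 1 / diag(H_betaS(x))`.
#'
#' `harmonic_preconditioner` combines the two through half the (scaled)
#' harmonic mean,
#' `D(x) = (D_MLEM^-1 + alpha D_betaS^-1)^-1
#'       = (x + delta) / (A'1 + alpha * diag(H_betaS(x)) * (x + delta))`,
#' which is bounded above by each constituent:
#' `D <= min(D_MLEM, alpha^-1 D_betaS)` componentwise. When the data and
#' prior diagonals each approximate their Hessians, the harmonic mean
#' approximates the curvature of the full smooth objective, which is what
#' lets unit-scale stepsizes work across regularisation strengths.
#'
#' @param x non-negative image array.
#' @param sensitivity strictly positive sensitivity image `A' 1`.
#' @param delta non-negative floor constant (strictly positive required
#'   when `x` can be zero).
#' @param rdp an [rdp_params()] object with `beta > 0` (the prior
#'   curvature is `beta * rdp_diag_hessian`).
#' @param alpha positive weight of the prior curvature in the harmonic
#'   combination (default 1).
#' @return image array of strictly positive diagonal entries.
#' @export
mlem_preconditioner <- function(x, sensitivity, delta) {
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  if (delta < 0) stop("delta must be non-negative")
  if (any(sensitivity <= 0)) stop("sensitivity must be strictly positive")
  d <- (xa + delta) / sensitivity
  if (any(d <= 0))
    stop("preconditioner has non-positive entries; use delta > 0")
  array(d, dim = dim(xa))
}

#' @rdname mlem_preconditioner
#' @export
prior_preconditioner <- function(x, rdp) {
  if (rdp$beta <= 0)
    stop("prior preconditioner requires beta > 0; use the MLEM form")
  h <- rdp$beta * rdp_diag_hessian(x, rdp)
  if (any(h <= 0))
    stop("diagonal prior Hessian has non-positive entries")
  1 / h
}

#' @rdname mlem_preconditioner
#' @export
harmonic_preconditioner <- function(x, sensitivity, rdp, alpha = 1,
                                    delta = 1e-6) {
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  if (alpha <= 0) stop("alpha must be positive")
  if (delta < 0) stop("delta must be non-negative")
  if (any(sensitivity <= 0)) stop("sensitivity must be strictly positive")
  h <- if (rdp$beta > 0) rdp$beta * rdp_diag_hessian(xa, rdp) else 0
  d <- (xa + delta) / (sensitivity + alpha * h * (xa + delta))
  if (any(d <= 0))
    stop("preconditioner has non-positive entries; use delta > 0")
  array(d, dim = dim(xa))
}

#' Epoch-based preconditioner update schedule
#'
#' The diagonal stabilises after the first few epochs, so it is
#' recomputed only at the start of the listed epochs and kept frozen
#' otherwise.
#'
#' @param epoch current epoch number (1-based, evaluated at its start).
#' @param update_epochs integer vector of epochs at which to recompute.
#' @param current current preconditioner (image array), or `NULL` before
#'   the first computation.
#' @param compute zero-argument function returning the freshly computed
#'   preconditioner at the current iterate.
#' @return image array: either `current` unchanged or the recomputed
#'   diagonal.
#' @export
preconditioner_schedule <- function(epoch, update_epochs, current, compute) {
  if (epoch < 1) stop("epoch must be >= 1")
  if (is.null(current) || epoch %in% update_epochs) compute() else current
}
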