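#' Relative difference prior parameters
#'
#' The prior on a non-negative image `x` is
#' `S(x) = 1/2 * sum_i sum_{j in N_i} w_ij k_i k_j (x_i - x_j)^2 /
#' (x_i + x_j + gamma |x_i - x_j| + epsilon)`:
#' a smooth convex neighbourhood penalty whose weight on a voxel-pair
#' difference shrinks as the total activity of the pair grows, so smoothing
#' is strongest in low-activity regions. `gamma` controls edge
#' preservation (for `gamma |d| >> s` the penalty behaves like total
#' variation scaled by `1/gamma`); `epsilon > 0` keeps it twice
#' continuously differentiable.
#'
#' @param beta non-negative global regularisation weight.
#' @param gamma positive edge-preservation parameter (default 2, common
#'   practice for this prior).
#' @param epsilon positive smoothing constant (default 1e-9, in squared
#'   activity units; effectively only active where both voxels are ~0).
#' @param kappa optional per-voxel positive weight array (or scalar) used
#'   as `k_i k_j` on each edge; defaults to 1. Typically a
#'   perturbation-response factor derived from the data Hessian.
#' @param neighborhood `"full"` (8-neighbourhood in 2D, 26 in 3D) or
#'   `"axial"` (4 in 2D, 6 in 3D).
#' @return object of class `rdp_params`.
#' @export
rdp_params <- function(beta, gamma = 2, epsilon = 1e-9, kappa = NULL,
                       neighborhood = c("full", "axial")) {
  neighborhood <- match.arg(neighborhood)
  if (beta < 0) stop("beta must be non-negative")
  if (gamma <= 0) stop("gamma must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (!is.null(kappa) && any(kappa <= 0)) stop("kappa must be positive")
  structure(list(beta = beta, gamma = gamma, epsilon = epsilon,
                 kappa = kappa, neighborhood = neighborhood,
                 cache = new.env(parent = emptyenv())),
            class = "rdp_params")
}

#' @export
print.rdp_params <- function(x, ...) {
  cat("<rdp_params> beta=", x$beta, " gamma=", x$gamma,
      " epsilon=", x$epsilon, " neighborhood=", x$neighborhood,
      if (is.null(x$kappa)) " kappa=1" else " kappa=supplied",
      "\n", sep = "")
  invisible(x)
}

# Half-offsets of the neighbourhood: each unordered voxel pair appears in
# exactly one group. Edge weight w = 1 / Euclidean offset length (voxels).
rdp_half_offsets <- function(nd, neighborhood) {
  grid <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  keep <- apply(grid, 1L, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[max(which(o != 0))] > 0  # lexicographic half-space
  })
  offs <- grid[keep, , drop = FALSE]
  if (neighborhood == "axial")
    offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  offs
}

# Edge list per half-offset for a given image shape; neighbours outside the
# grid are skipped (no padding), preserving weight symmetry.
rdp_edges <- function(params, shape) {
  key <- paste(shape, collapse = "x")
  cached <- params$cache[[key]]
  if (!is.null(cached)) return(cached)
  nd <- length(shape)
  offs <- rdp_half_offsets(nd, params$neighborhood)
  stride <- cumprod(c(1, shape[-nd]))
  groups <- lapply(seq_len(nrow(offs)), function(r) {
    off <- offs[r, ]
    ranges <- lapply(seq_len(nd), function(a) {
      lo <- max(1L, 1L - off[a])
      hi <- min(shape[a], shape[a] - off[a])
      if (hi < lo) integer(0) else seq.int(lo, hi)
    })
    if (any(lengths(ranges) == 0L)) return(NULL)
    co <- as.matrix(do.call(expand.grid, ranges))
    i <- as.integer(1 + (co - 1) %*% stride)
    j <- as.integer(i + sum(off * stride))
    list(i = i, j = j, w = 1 / sqrt(sum(off^2)))
  })
  groups <- Filter(Negate(is.null), groups)
  params$cache[[key]] <- groups
  groups
}

edge_kappa <- function(params, i, j) {
  if (is.null(params$kappa)) return(1)
  kv <- as.vector(params$kappa)
  if (length(kv) == 1L) return(kv^2)
  kv[i] * kv[j]
}

#' Pointwise Kullback-Leibler term of the Poisson log-likelihood
#'
#' `d(s, t) = s - t + t log(t/s)` for `t > 0, s > 0`; `s` for `t = 0`;
#' `+Inf` for `t > 0, s = 0`. Always non-negative, zero iff `s = t`.
#'
#' @param s non-negative expected value(s).
#' @param t non-negative observed count(s).
#' @return numeric vector (extended reals: may contain `Inf`).
#' @export
kl_term <- function(s, t) {
  if (any(s < 0) || any(t < 0)) stop("kl_term arguments must be non-negative")
  n <- max(length(s), length(t))
  s <- rep_len(s, n); t <- rep_len(t, n)
  out <- ifelse(t == 0, s,
                ifelse(s == 0, Inf, s - t + t * log(t / s)))
  out
}

#' Objective bundle: model + data + partition + prior
#'
#' Packages everything needed to evaluate the penalized objective
#' `J(x) = D(Ax + r, y) + beta * S(x)` and its subset components
#' `J_i(x) = D_i(x) + (beta/n) S(x)`. Per-subset row restrictions of the
#' system matrix and the subset sensitivities `A_i' 1` are precomputed.
#'
#' @param model a [build_projector()] result.
#' @param data a [sinogram()].
#' @param partition a [partition_views()] result (must match the data's
#'   view count).
#' @param rdp an [rdp_params()] object.
#' @return object of class `objective_bundle`.
#' @export
build_bundle <- function(model, data, partition, rdp) {
  stopifnot(inherits(model, "forward_model"), inherits(data, "sinogram"),
            inherits(partition, "subset_partition"),
            inherits(rdp, "rdp_params"))
  if (data$n_views != model$n_views || partition$n_views != model$n_views)
    stop("view counts of model, data and partition must agree")
  if (data$n_radial != model$n_radial)
    stop("radial bin counts of model and data must agree")
  n <- partition$n_subsets
  rows <- lapply(partition$view_lists,
                 function(v) which(model$view_of_row %in% v))
  subA <- lapply(rows, function(r) model$A[r, , drop = FALSE])
  subAt <- lapply(subA, Matrix::t)
  sens <- lapply(subA, function(M) as.vector(Matrix::colSums(M)))
  structure(list(model = model, data = data, partition = partition,
                 rdp = rdp, n_subsets = n,
                 subset_rows = rows, subset_A = subA, subset_At = subAt,
                 subset_sens = sens,
                 shape = model$image_shape,
                 nvox = prod(model$image_shape)),
            class = "objective_bundle")
}

#' @export
print.objective_bundle <- function(x, ...) {
  cat("<objective_bundle> ", paste(x$shape, collapse = " x "),
      " image, ", x$n_subsets, " subsets, beta=", x$rdp$beta, "\n", sep = "")
  invisible(x)
}

check_subset <- function(bundle, subset) {
  if (is.null(subset)) return(NULL)
  subset <- as.integer(subset)
  if (subset < 0L || subset >= bundle$n_subsets)
    stop("subset index out of range [0, ", bundle$n_subsets - 1L, "]")
  subset + 1L
}

#' Poisson (KL) data fidelity and its gradient
#'
#' `data_fidelity` evaluates `D_i(x) = sum_{j in S_i} d(A_j x + r_j, y_j)`
#' over the bins of one subset (all bins when `subset` is `NULL`).
#' `data_fidelity_gradient` returns the image-space gradient
#' `A_i' (1 - y_i / (A_i x + r_i))`.
#'
#' @param x image array (non-negative).
#' @param bundle an [build_bundle()] object.
#' @param subset 0-based subset index, or `NULL` for the full data.
#' @return scalar value / gradient image array.
#' @export
data_fidelity <- function(x, bundle, subset = NULL) {
  xv <- as.vector(if (inherits(x, "voxel_image")) img_values(x) else x)
  if (any(xv < 0)) stop("x must be non-negative")
  s1 <- check_subset(bundle, subset)
  if (is.null(s1)) {
    lam <- as.vector(bundle$model$A %*% xv) + as.vector(bundle$data$background)
    y <- as.vector(bundle$data$counts)
  } else {
    r <- bundle$subset_rows[[s1]]
    lam <- as.vector(bundle$subset_A[[s1]] %*% xv) +
      as.vector(bundle$data$background)[r]
    y <- as.vector(bundle$data$counts)[r]
  }
  sum(kl_term(lam, y))
}

#' @rdname data_fidelity
#' @export
data_fidelity_gradient <- function(x, bundle, subset = NULL) {
  xv <- as.vector(if (inherits(x, "voxel_image")) img_values(x) else x)
  if (any(xv < 0)) stop("x must be non-negative")
  s1 <- check_subset(bundle, subset)
  if (is.null(s1)) {
    lam <- as.vector(bundle$model$A %*% xv) + as.vector(bundle$data$background)
    if (any(lam <= 0)) stop("non-positive expected counts")
    resid <- 1 - as.vector(bundle$data$counts) / lam
    g <- as.vector(bundle$model$At %*% resid)
  } else {
    r <- bundle$subset_rows[[s1]]
    lam <- as.vector(bundle$subset_A[[s1]] %*% xv) +
      as.vector(bundle$data$background)[r]
    if (any(lam <= 0)) stop("non-positive expected counts")
    resid <- 1 - as.vector(bundle$data$counts)[r] / lam
    g <- as.vector(bundle$subset_At[[s1]] %*% resid)
  }
  array(g, dim = bundle$shape)
}

#' Relative difference prior: value, gradient, diagonal Hessian
#'
#' Analytic derivatives of the prior described in [rdp_params()]. With
#' `d = x_i - x_j`, `s = x_i + x_j`, `u = s + gamma |d| + epsilon` and
#' `c = 1 + gamma sign(d)` (with `sign(0) = 0`), each edge contributes
#' `(2 d u - d^2 c) / u^2` to the gradient at voxel `i` and
#' `2 (2 x_j + epsilon)^2 / u^3` to the diagonal Hessian at voxel `i`
#' (neighbour values held fixed); the latter closed form is strictly
#' positive, which is what makes the prior-aware preconditioner
#' well-defined everywhere.
#'
#' @param x non-negative image array.
#' @param rdp an [rdp_params()] object (the global `beta` is *not* applied
#'   here; these are derivatives of `S`, not `beta S`).
#' @return scalar / gradient array / diagonal Hessian array.
#' @export
rdp_value <- function(x, rdp) {
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  if (any(xa < 0)) stop("x must be non-negative")
  xv <- as.vector(xa)
  total <- 0
  for (e in rdp_edges(rdp, dim(xa))) {
    d <- xv[e$i] - xv[e$j]
    u <- xv[e$i] + xv[e$j] + rdp$gamma * abs(d) + rdp$epsilon
    total <- total + sum(e$w * edge_kappa(rdp, e$i, e$j) * d^2 / u)
  }
  total
}

#' @rdname rdp_value
#' @export
rdp_gradient <- function(x, rdp) {
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  if (any(xa < 0)) stop("x must be non-negative")
  xv <- as.vector(xa)
  g <- numeric(length(xv))
  for (e in rdp_edges(rdp, dim(xa))) {
    d <- xv[e$i] - xv[e$j]
    u <- xv[e$i] + xv[e$j] + rdp$gamma * abs(d) + rdp$epsilon
    wk <- e$w * edge_kappa(rdp, e$i, e$j)
    sg <- sign(d)
    gi <- wk * (2 * d * u - d^2 * (1 + rdp$gamma * sg)) / u^2
    gj <- wk * (-2 * d * u - d^2 * (1 - rdp$gamma * sg)) / u^2
    g[e$i] <- g[e$i] + gi
    g[e$j] <- g[e$j] + gj
  }
  array(g, dim = dim(xa))
}

#' @rdname rdp_value
#' @export
rdp_diag_hessian <- function(x, rdp) {
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  if (any(xa < 0)) stop("x must be non-negative")
  xv <- as.vector(xa)
  h <- numeric(length(xv))
  for (e in rdp_edges(rdp, dim(xa))) {
    d <- xv[e$i] - xv[e$j]
    u <- xv[e$i] + xv[e$j] + rdp$gamma * abs(d) + rdp$epsilon
    wk <- e$w * edge_kappa(rdp, e$i, e$j)
    # second derivative of d^2/u in x_i reduces to 2 (u - c d)^2 / u^3
    # with u - c d = 2 x_j + epsilon (and symmetrically for x_j)
    h[e$i] <- h[e$i] + wk * 2 * (2 * xv[e$j] + rdp$epsilon)^2 / u^3
    h[e$j] <- h[e$j] + wk * 2 * (2 * xv[e$i] + rdp$epsilon)^2 / u^3
  }
  array(h, dim = dim(xa))
}

#' Subset gradient of the penalized objective
#'
#' `grad J_i(x) = grad D_i(x) + (beta/n) grad S(x)`; with `subset = NULL`
#' the full gradient `grad D(x) + beta grad S(x)`.
#'
#' @inheritParams data_fidelity
#' @return gradient image array.
#' @export
subset_gradient <- function(x, bundle, subset = NULL) {
  g <- data_fidelity_gradient(x, bundle, subset)
  b <- bundle$rdp$beta
  if (b > 0) {
    frac <- if (is.null(subset)) 1 else 1 / bundle$n_subsets
    g <- g + (b * frac) * rdp_gradient(x, bundle$rdp)
  }
  g
}

#' Penalized objective value
#'
#' `J(x) = D(Ax + r, y) + beta S(x)`.
#'
#' @inheritParams data_fidelity
#' @return scalar (may be `Inf` for infeasible images).
#' @export
objective_value <- function(x, bundle) {
  data_fidelity(x, bundle) + bundle$rdp$beta * rdp_value(x, bundle$rdp)
}
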