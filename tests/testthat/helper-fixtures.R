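# Small deterministic fixtures shared across the test files.

# toy forward model + Poisson data + bundle; everything seeded
toy_bundle <- function(shape = c(8L, 8L), n_views = 10L, n_radial = 12L,
                       n_subsets = 5L, beta = 0.05, gamma = 2,
                       epsilon = 1e-3, psf_fwhm_mm = 0, seed = 7L) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- build_projector(shape, 2, n_views, n_radial,
                       psf_fwhm_mm = psf_fwhm_mm)
  xtrue <- matrix(runif(prod(shape), 0.3, 2), shape[1], shape[2])
  lam <- forward_project(m, xtrue)
  bg <- matrix(0.4, n_views, n_radial)
  counts <- matrix(rpois(length(lam), lam + bg), n_views, n_radial)
  bundle <- build_bundle(m, sinogram(counts, bg),
                         partition_views(n_views, n_subsets),
                         rdp_params(beta = beta, gamma = gamma,
                                    epsilon = epsilon))
  list(model = m, bundle = bundle, xtrue = xtrue, lambda = lam, bg = bg)
}

# central finite differences of a scalar field
fd_gradient <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# second-order central differences of the diagonal
fd_diag_hessian <- function(f, x, h = 1e-4) {
  d <- x * 0
  f0 <- f(x)
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    d[i] <- (f(xp) - 2 * f0 + f(xm)) / h^2
  }
  d
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
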