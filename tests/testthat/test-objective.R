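test_that("pointwise KL term matches its closed form and sign structure", {
  expect_identical(kl_term(2, 2), 0)
  expect_identical(kl_term(3, 0), 3)
  expect_identical(kl_term(0, 1), Inf)
  expect_equal(kl_term(2, 1), 1 - log(2))
  expect_error(kl_term(-1, 1), "non-negative")
  with_seed(4, {
    s <- runif(200, 0, 5); t <- runif(200, 0, 5)
    v <- kl_term(s, t)
    expect_true(all(v >= 0))
    expect_true(all((v == 0) == (abs(s - t) < 1e-14)))
  })
})

test_that("data fidelity is separable over subsets and zero at an exact fit", {
  tb <- toy_bundle()
  x0 <- with_seed(5, matrix(runif(64, 0.2, 1.5), 8, 8))
  full <- data_fidelity(x0, tb$bundle)
  parts <- vapply(0:4, function(i) data_fidelity(x0, tb$bundle, i),
                  numeric(1))
  expect_lt(abs(full - sum(parts)), 1e-12 * full)
  # exact fit: counts equal to expectation
  exact <- build_bundle(tb$model, sinogram(tb$lambda + tb$bg, tb$bg),
                        tb$bundle$partition, tb$bundle$rdp)
  expect_equal(data_fidelity(tb$xtrue, exact), 0, tolerance = 1e-10)
  # x = 0: value is sum of d(r_j, y_j)
  expect_equal(data_fidelity(matrix(0, 8, 8), tb$bundle, 1),
               sum(kl_term(tb$bg[tb$bundle$subset_rows[[2]]],
                           tb$bundle$data$counts[tb$bundle$subset_rows[[2]]])))
  expect_error(data_fidelity(x0, tb$bundle, 5), "out of range")
})

test_that("data fidelity gradient matches finite differences and limits", {
  tb <- toy_bundle()
  x0 <- with_seed(6, matrix(runif(64, 0.2, 1.5), 8, 8))
  g <- data_fidelity_gradient(x0, tb$bundle, 2)
  gf <- fd_gradient(function(z) data_fidelity(z, tb$bundle, 2), x0)
  expect_lt(rel_err(g, gf), 1e-6)
  # exact fit is a stationary point
  exact <- build_bundle(tb$model, sinogram(tb$lambda + tb$bg, tb$bg),
                        tb$bundle$partition, tb$bundle$rdp)
  expect_lt(max(abs(data_fidelity_gradient(tb$xtrue, exact))), 1e-9)
  # y = 0: gradient equals the subset sensitivity
  zero <- build_bundle(tb$model, sinogram(0 * tb$bg, tb$bg),
                       tb$bundle$partition, tb$bundle$rdp)
  expect_equal(as.vector(data_fidelity_gradient(x0, zero, 1)),
               as.vector(subset_sensitivity(tb$model,
                                            tb$bundle$partition$view_lists[[2]])),
               tolerance = 1e-12)
})

test_that("prior value matches hand-computed pair examples", {
  r <- rdp_params(beta = 1, gamma = 2, epsilon = 1e-12)
  expect_equal(rdp_value(matrix(c(2, 0), 1, 2), r), 2 / 3,
               tolerance = 1e-9)
  expect_identical(rdp_value(matrix(3, 4, 4), r), 0)
  # TV regime: phi -> |d| / gamma when s << gamma |d|
  rtv <- rdp_params(beta = 1, gamma = 1000, epsilon = 1e-15)
  expect_equal(rdp_value(matrix(c(1, 0), 1, 2), rtv), 1 / 1000,
               tolerance = 2e-3)
  expect_error(rdp_value(matrix(c(-1, 1), 1, 2), r), "non-negative")
})

test_that("prior approaches the scaled total variation for large gamma", {
  with_seed(8, {
    x <- matrix(sample(c(0.5, 2, 5), 36, replace = TRUE), 6, 6)
    gam <- 1e4
    r <- rdp_params(beta = 1, gamma = gam, epsilon = 1e-15)
    tv <- 0
    for (e in petrdp:::rdp_edges(r, dim(x)))
      tv <- tv + sum(e$w * abs(x[e$i] - x[e$j]))
    expect_lt(abs(rdp_value(x, r) - tv / gam) / (tv / gam), 0.01)
  })
})

test_that("prior is invariant under grid relabelings consistent with the neighbourhood", {
  with_seed(9, {
    x <- matrix(runif(49, 0, 3), 7, 7)
    r <- rdp_params(beta = 1, gamma = 2, epsilon = 1e-6)
    expect_equal(rdp_value(t(x), r), rdp_value(x, r), tolerance = 1e-12)
    expect_equal(rdp_value(x[7:1, ], r), rdp_value(x, r), tolerance = 1e-12)
    expect_equal(rdp_value(x[, 7:1], r), rdp_value(x, r), tolerance = 1e-12)
  })
})

test_that("prior gradient and diagonal Hessian match finite differences", {
  r <- rdp_params(beta = 1, gamma = 2, epsilon = 1e-3)
  expect_equal(rdp_gradient(matrix(c(2, 0), 1, 2),
                            rdp_params(1, 2, 1e-12))[1], 1 / 3,
               tolerance = 1e-6)
  expect_identical(rdp_gradient(matrix(1, 5, 5), r), array(0, c(5, 5)))
  for (seed in 1:20) {
    x <- with_seed(100 + seed, matrix(runif(36, 0.05, 2), 6, 6))
    g <- rdp_gradient(x, r)
    gf <- fd_gradient(function(z) rdp_value(z, r), x)
    expect_lt(rel_err(g, gf), 1e-6)
    h <- rdp_diag_hessian(x, r)
    hf <- fd_diag_hessian(function(z) rdp_value(z, r), x)
    expect_lt(rel_err(h, hf), 1e-5)
  }
})

test_that("prior curvature has the closed form 2/(2c+eps) at equal voxels and grows as c -> 0", {
  eps <- 1e-3
  r <- rdp_params(beta = 1, gamma = 2, epsilon = eps)
  vals <- vapply(c(2, 1, 0.5, 0.1, 0),
                 function(c0) rdp_diag_hessian(matrix(c0, 1, 2), r)[1],
                 numeric(1))
  expect_equal(vals, 2 * (2 * c(2, 1, 0.5, 0.1, 0) + eps)^2 /
                 (2 * c(2, 1, 0.5, 0.1, 0) + eps)^3, tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))
})

test_that("kappa and 3D neighbourhoods enter the prior consistently", {
  with_seed(10, {
    x <- matrix(runif(16, 0.1, 2), 4, 4)
    kap <- matrix(runif(16, 0.5, 2), 4, 4)
    rk <- rdp_params(1, 2, 1e-3, kappa = kap)
    gf <- fd_gradient(function(z) rdp_value(z, rk), x)
    expect_lt(rel_err(rdp_gradient(x, rk), gf), 1e-6)
    # 3D: 26-neighbourhood, gradient still matches finite differences
    x3 <- array(runif(27, 0.1, 2), c(3, 3, 3))
    r3 <- rdp_params(1, 2, 1e-3)
    expect_lt(rel_err(rdp_gradient(x3, r3),
                      fd_gradient(function(z) rdp_value(z, r3), x3)), 1e-6)
  })
})

test_that("subset gradients of the penalized objective sum and scale correctly", {
  tb <- toy_bundle(beta = 0.1)
  x0 <- with_seed(11, matrix(runif(64, 0.2, 1.5), 8, 8))
  gfull <- subset_gradient(x0, tb$bundle)
  gs <- Reduce(`+`, lapply(0:4, function(i) subset_gradient(x0, tb$bundle, i)))
  expect_lt(rel_err(gs, gfull), 1e-12)
  # beta = 0 reduces to the data gradient
  tb0 <- toy_bundle(beta = 0)
  expect_identical(subset_gradient(x0, tb0$bundle, 3),
                   data_fidelity_gradient(x0, tb0$bundle, 3))
  # finite differences of D_i + (beta/n) S
  Ji <- function(z) data_fidelity(z, tb$bundle, 2) +
    tb$bundle$rdp$beta / 5 * rdp_value(z, tb$bundle$rdp)
  expect_lt(rel_err(subset_gradient(x0, tb$bundle, 2),
                    fd_gradient(Ji, x0)), 1e-6)
})
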