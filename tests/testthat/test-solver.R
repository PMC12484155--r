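test_that("the projected preconditioned step has its closed form", {
  x <- matrix(c(1, 2, 0, 0.5), 2, 2)
  D <- matrix(1, 2, 2)
  expect_identical(prox_step(x, 1, D, 0 * x), x)
  expect_identical(prox_step(0 * x, 1, D, abs(x) + 1),
                   array(0, c(2, 2)))
  expect_equal(prox_step(matrix(1, 1, 1), 1, matrix(1 / 6, 1, 1),
                         matrix(3, 1, 1))[1], 0.5)
  expect_error(prox_step(x, 1, D, matrix(NaN, 2, 2)), "non-finite")
  expect_error(prox_step(x, 0, D, x), "positive")
})

test_that("OSEM is a fixed point on noise-free data and stays non-negative", {
  tb <- toy_bundle(n_views = 12L, n_subsets = 3L, beta = 0)
  exact <- build_bundle(tb$model, sinogram(tb$lambda + tb$bg, tb$bg),
                        tb$bundle$partition, tb$bundle$rdp)
  xo <- osem_initialize(exact, n_subsets = 3, x0 = tb$xtrue)
  expect_lt(rel_err(xo, tb$xtrue), 1e-12)
  x1 <- osem_initialize(tb$bundle, n_subsets = 5)
  expect_true(all(x1 >= 0))
  expect_error(osem_initialize(tb$bundle, x0 = 0 * tb$xtrue), "positive")
})

test_that("one-voxel one-bin OSEM reduces to the scalar EM update", {
  m <- build_projector(c(1L, 1L), 2, 1, 1)
  a <- as.numeric(m$A[1, 1])
  y <- 7; r <- 0.5; x0 <- 2
  bun <- build_bundle(m, sinogram(matrix(y, 1, 1), matrix(r, 1, 1)),
                      partition_views(1, 1), rdp_params(beta = 0))
  xo <- osem_initialize(bun, n_subsets = 1, x0 = matrix(x0, 1, 1))
  expect_equal(xo[1], x0 / a * (a * y / (a * x0 + r)))
})

test_that("with no prior, unit step and the EM diagonal the loop is exactly MLEM", {
  with_seed(30, {
    m <- build_projector(c(16L, 16L), 2, 12, 24)
    xtrue <- matrix(runif(256, 0.2, 2), 16, 16)
    lam <- forward_project(m, xtrue)
    bg <- matrix(0.5, 12, 24)
    sino <- sinogram(matrix(rpois(288, lam + bg), 12, 24), bg)
    bun <- build_bundle(m, sino, partition_views(12, 1),
                        rdp_params(beta = 0))
    x0 <- matrix(1, 16, 16)
    xm <- x0
    sens <- subset_sensitivity(m)
    for (it in 1:20) {
      l <- forward_project(m, xm) + bg
      xm <- xm / sens * back_project(m, sino$counts / l)
    }
    cfg <- recon_config(estimator = "sgd", n_epochs = 20,
                        stepsize_kind = "constant", tau0 = 1,
                        precond_kind = "mlem", delta = 0,
                        precond_update_epochs = 1:20,
                        objective_every = 1000L,
                        stop_at_threshold = FALSE)
    fit <- run_algorithm(bun, cfg, x0 = x0)
    expect_lt(rel_err(as.array(fit$image), xm), 1e-10)
  })
})

test_that("full-gradient descent with small constant steps decreases the objective", {
  with_seed(31, {
    m <- build_projector(c(32L, 32L), 2, 24, 48, psf_fwhm_mm = 3)
    xtrue <- matrix(runif(1024, 0.2, 2), 32, 32)
    lam <- forward_project(m, xtrue)
    bg <- matrix(0.4, 24, 48)
    sino <- sinogram(matrix(rpois(length(lam), lam + bg), 24, 48), bg)
    bun <- build_bundle(m, sino, partition_views(24, 1),
                        rdp_params(beta = 0.02, gamma = 2,
                                   epsilon = 1e-3))
    cfg <- recon_config(estimator = "sgd", n_epochs = 50,
                        stepsize_kind = "constant", tau0 = 0.4,
                        precond_kind = "harmonic",
                        objective_every = 1L, stop_at_threshold = FALSE)
    fit <- run_algorithm(bun, cfg)
    obj <- fit$history$objective
    expect_true(all(diff(obj) <= 1e-8 * abs(obj[-length(obj)])))
    expect_true(all(is.finite(obj)))
    expect_true(all(as.array(fit$image) >= 0))
  })
})

test_that("runs are bit-reproducible under a fixed seed and config", {
  tb <- toy_bundle(n_views = 12L, n_subsets = 4L, beta = 0.05)
  cfg <- recon_config(estimator = "svrg", n_epochs = 6,
                      sampler = "uniform_without", seed = 42,
                      objective_every = 4L, stop_at_threshold = FALSE)
  f1 <- run_algorithm(tb$bundle, cfg)
  f2 <- run_algorithm(tb$bundle, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(as.array(f1$image), as.array(f2$image))
})

test_that("the divergence guard aborts runs whose objective explodes", {
  tb <- toy_bundle(n_views = 12L, n_subsets = 4L, beta = 0.05)
  cfg <- recon_config(estimator = "sgd", n_epochs = 30,
                      stepsize_kind = "constant", tau0 = 500,
                      precond_kind = "mlem",
                      objective_every = 1L, stop_at_threshold = FALSE)
  fit <- run_algorithm(tb$bundle, cfg)
  expect_true(fit$diverged)
  expect_lt(nrow(fit$history), 30 * 4)
})

test_that("the quasi-Newton reference satisfies the stationarity conditions", {
  tb <- toy_bundle(n_views = 12L, n_subsets = 3L, beta = 0.05,
                   shape = c(16L, 16L), n_radial = 24L, seed = 30)
  ref <- reference_reconstruction(tb$bundle, 500)
  x <- as.array(ref$image)
  g <- subset_gradient(x, tb$bundle)
  gp <- ifelse(x > 1e-8, g, pmin(g, 0))   # projected onto feasible directions
  g0 <- subset_gradient(matrix(mean(x), 16, 16), tb$bundle)
  expect_lt(sqrt(sum(gp^2)), 1e-4 * sqrt(sum(g0^2)))
  # convexity: two different positive starts give the same solution
  ref2 <- reference_reconstruction(tb$bundle, 500,
                                   x0 = matrix(2, 16, 16))
  expect_lt(sqrt(mean((x - as.array(ref2$image))^2)) / mean(x), 1e-4)
})

test_that("a dominant prior drives the reference toward a constant image", {
  tb <- toy_bundle(n_views = 12L, n_subsets = 3L, beta = 0, seed = 33)
  strong <- build_bundle(tb$model, tb$bundle$data, tb$bundle$partition,
                         rdp_params(beta = 5e3, gamma = 2,
                                    epsilon = 1e-3))
  ref <- reference_reconstruction(strong, 500)
  x <- as.array(ref$image)
  supp <- subset_sensitivity(tb$model) > 0
  expect_lt(stats::sd(x[supp]) / mean(x[supp]), 0.05)
})
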