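test_that("phantom rasterisation matches analytic areas, mask and normalisation", {
  sp <- phantom_spec(
    list(list(center = c(0, 0), semi_axes = c(30, 30), activity = 2)),
    shape = c(64L, 64L), voxel_size_mm = 1)
  ph <- make_phantom(sp)
  expect_lt(abs(sum(ph$mask) - pi * 30^2) / (pi * 30^2), 0.02)
  expect_identical(ph$norm_value, 2)
  expect_true(all(as.array(ph$image)[!ph$mask] == 0))
  ph2 <- make_phantom(default_phantom_spec())
  areas <- vapply(default_phantom_spec()$ellipses,
                  function(e) pi * prod(e$semi_axes), numeric(1))
  expect_identical(ph2$norm_value,
                   default_phantom_spec()$ellipses[[which.max(areas)]]$activity)
  expect_error(phantom_spec(list(), c(64L, 64L)), "at least one")
  expect_error(phantom_spec(
    list(list(center = c(70, 0), semi_axes = c(30, 30), activity = 1)),
    shape = c(64L, 64L), voxel_size_mm = 1), "beyond")
})

test_that("simulated acquisitions have the requested count statistics", {
  ph <- make_phantom(default_phantom_spec())
  m <- build_projector(c(64L, 64L), 2.5, 48, 96, psf_fwhm_mm = 4)
  acq <- simulate_acquisition(ph$image, m, 2e5,
                              background_fraction = 0.25, seed = 9)
  expected_total <- 2e5 * (1 + 0.25 / 0.75)
  expect_lt(abs(sum(acq$sinogram$counts) - expected_total),
            4 * sqrt(expected_total))
  expect_equal(sum(acq$sinogram$background), 0.25 / 0.75 * 2e5,
               tolerance = 1e-6)
  expect_true(all(acq$sinogram$background > 0))
  # fixed seed -> identical counts; different seed -> different draws
  acq2 <- simulate_acquisition(ph$image, m, 2e5, 0.25, seed = 9)
  expect_identical(acq$sinogram$counts, acq2$sinogram$counts)
  acq3 <- simulate_acquisition(ph$image, m, 2e5, 0.25, seed = 10)
  expect_false(identical(acq$sinogram$counts, acq3$sinogram$counts))
  # zero background fraction: the floor keeps r strictly positive
  acq0 <- simulate_acquisition(ph$image, m, 2e5, 0, seed = 9)
  expect_true(all(acq0$sinogram$background > 0))
  expect_error(simulate_acquisition(0 * as.array(ph$image), m, 2e5),
               "zero")
})

test_that("the count-level scaling rule for beta is exact", {
  expect_identical(scale_beta(1, 3e7), 2e-4)
  expect_identical(scale_beta(16, 3e7), 3.2e-3)
  expect_equal(scale_beta(4, 1e7), 4 * 2e-4 / 3, tolerance = 1e-15)
  expect_error(scale_beta(-1, 1e7), "positive")
})

test_that("NRMSE has the stated algebraic properties", {
  with_seed(40, {
    x <- matrix(runif(64), 8, 8)
    mask <- matrix(rep(c(TRUE, FALSE), 32), 8, 8)
    expect_identical(nrmse(x, x, mask, 2), 0)
    expect_equal(nrmse(x + 0.3, x, mask, 1.5), 0.3 / 1.5)
    expect_equal(nrmse(3 * x, 3 * (x + 0.1), mask, 3 * 2),
                 nrmse(x, x + 0.1, mask, 2))
    expect_error(nrmse(x, x, mask & FALSE, 1), "at least one")
    expect_error(nrmse(x, x[1:4, 1:4], mask, 1), "match")
  })
})

test_that("full gradients recover the reference on a noise-free instance", {
  # well-conditioned 32x32 phantom, counts equal to their expectation
  sp <- phantom_spec(
    list(list(center = c(0, 0), semi_axes = c(26, 20), activity = 1),
         list(center = c(8, 5), semi_axes = c(7, 7), activity = 2)),
    shape = c(32L, 32L), voxel_size_mm = 2, target_true_counts = 1e5)
  ph <- make_phantom(sp)
  m <- build_projector(c(32L, 32L), 2, 48, 64, psf_fwhm_mm = 0)
  lam <- forward_project(m, ph$image)
  sc <- 1e5 / sum(lam)
  lam <- lam * sc
  bg <- matrix(mean(lam) * 0.2, 48, 64)
  bun <- build_bundle(m, sinogram(lam + bg, bg), partition_views(48, 1),
                      rdp_params(beta = 0.05, gamma = 2, epsilon = 1e-3))
  ref <- reference_reconstruction(bun, 500)
  cfg <- recon_config(estimator = "sgd", n_epochs = 2000,
                      stepsize_kind = "constant", tau0 = 1.5,
                      precond_kind = "harmonic",
                      precond_update_epochs = c(1, 2, 3, 10, 30, 100, 300),
                      nrmse_threshold = 1e-3,
                      objective_every = 500L)
  fit <- run_algorithm(bun, cfg,
                       reference = list(image = ref$image, mask = ph$mask,
                                        norm_value = ph$norm_value * sc))
  expect_true(fit$converged)
})

test_that("a one-cell grid reproduces a single reconstruction and failures are recorded", {
  grid <- tibble::tibble(estimator = c("svrg", "nonsense"),
                         n_epochs = c(3, 3), seed = c(1, 1))
  sp <- phantom_spec(
    list(list(center = c(0, 0), semi_axes = c(24, 20), activity = 1),
         list(center = c(8, 5), semi_axes = c(6, 6), activity = 2.5)),
    shape = c(32L, 32L), voxel_size_mm = 2, target_true_counts = 5e4,
    beta_tilde = 4)
  res <- run_experiment_grid(grid, spec = sp, n_views = 24L,
                             n_radial = 48L, reference_iterations = 200)
  expect_identical(nrow(res), 2L)
  expect_true(is.na(res$error[1]))
  expect_false(is.na(res$error[2]))
  expect_true(is.finite(res$final_nrmse[1]))
})
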