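#' Assemble the desk-scale simulation benchmark
#'
#' Builds everything needed to run and score reconstructions of a
#' simulated acquisition: rasterises the phantom, builds the forward
#' model (with water attenuation over the phantom support by default),
#' simulates the Poisson acquisition, derives the prior weight factors
#' `kappa` from the data (see [kappa_perturbation()]), scales `beta` by
#' the count level ([scale_beta()]) and packages an [build_bundle()].
#'
#' The returned `truth` and `norm_value` are expressed on the
#' reconstruction scale (the phantom times the acquisition's
#' `true_scale`), so they can be compared directly with reconstructed
#' images.
#'
#' @param spec a [phantom_spec()] (defaults to
#'   [default_phantom_spec()]).
#' @param n_views,n_radial sinogram geometry (defaults 96 views, 128
#'   radial bins).
#' @param psf_fwhm_mm image-space resolution model (default 4 mm).
#' @param attenuation apply water attenuation over the phantom support?
#' @param water_mu linear attenuation coefficient of water at 511 keV
#'   (1/mm).
#' @param background_fraction fraction of total counts due to background.
#' @param data_seed seed for the Poisson acquisition.
#' @param n_subsets subset count; default: divisor of `n_views` closest
#'   to 25.
#' @param gamma,epsilon prior shape parameters, see [rdp_params()].
#' @param kappa `"perturbation"` (data-derived weights, the default) or
#'   `"uniform"` (all ones, no rescaling).
#' @param kappa_target_ratio calibration constant for the overall scale
#'   of the perturbation-response `kappa`: the median ratio of prior to
#'   likelihood diagonal curvature over the phantom support, evaluated
#'   at the OSEM initialiser with relative regularisation strength
#'   `beta_tilde = 1` (default 0.1). With this normalisation the
#'   `beta_tilde` sweep `{1, 4, 16}` spans weak (0.1) to strong (1.6)
#'   regularisation relative to the data curvature, independently of the
#'   count level and of the desk-scale geometry. See the methods
#'   vignette for the rationale.
#' @return list of class `benchmark_setup` with elements `bundle`,
#'   `model`, `acquisition`, `truth`, `mask`, `norm_value`, `osem_init`,
#'   `beta` and `spec`.
#' @export
setup_benchmark <- function(spec = default_phantom_spec(),
                            n_views = 96L, n_radial = 128L,
                            psf_fwhm_mm = 4,
                            attenuation = TRUE, water_mu = 0.0096,
                            background_fraction = 0.25,
                            data_seed = 1L,
                            n_subsets = NULL,
                            gamma = 2, epsilon = 1e-9,
                            kappa = c("perturbation", "uniform"),
                            kappa_target_ratio = 0.1) {
  kappa <- match.arg(kappa)
  ph <- make_phantom(spec)
  atten_img <- NULL
  if (attenuation)
    atten_img <- voxel_image(water_mu * ph$mask, spec$voxel_size_mm)
  model <- build_projector(spec$shape, spec$voxel_size_mm,
                           n_views, n_radial, psf_fwhm_mm, atten_img)
  acq <- simulate_acquisition(ph$image, model, spec$target_true_counts,
                              background_fraction, seed = data_seed)
  beta <- scale_beta(spec$beta_tilde, spec$target_true_counts)
  if (is.null(n_subsets)) n_subsets <- choose_num_subsets(n_views, 25)
  part <- partition_views(n_views, n_subsets)

  # OSEM initialisation on the pure likelihood, then data-derived kappa
  ml_bundle <- build_bundle(model, acq$sinogram, part,
                            rdp_params(beta = 0, gamma = gamma,
                                       epsilon = epsilon))
  x_init <- osem_initialize(ml_bundle)
  kap <- NULL
  if (kappa == "perturbation") {
    k0 <- kappa_perturbation(model, acq$sinogram, x_init)
    # calibrate the free overall scale of kappa: median prior/likelihood
    # diagonal curvature ratio over the support = kappa_target_ratio at
    # beta_tilde = 1
    hP <- rdp_diag_hessian(x_init, rdp_params(beta = 1, gamma = gamma,
                                              epsilon = epsilon,
                                              kappa = k0))
    yhat <- as.vector(model$A %*% as.vector(x_init)) +
      as.vector(acq$sinogram$background)
    wf <- as.vector(acq$sinogram$counts) / yhat^2
    hD <- as.vector(Matrix::colSums(model$A^2 * wf))
    sel <- as.vector(ph$mask) & hD > 0
    r0 <- stats::median(scale_beta(1, spec$target_true_counts) *
                          as.vector(hP)[sel] / hD[sel])
    kap <- k0 * sqrt(kappa_target_ratio / r0)
  }
  rdp <- rdp_params(beta = beta, gamma = gamma, epsilon = epsilon,
                    kappa = kap)
  bundle <- build_bundle(model, acq$sinogram, part, rdp)

  structure(list(bundle = bundle, model = model, acquisition = acq,
                 truth = voxel_image(img_values(ph$image) * acq$true_scale,
                                     spec$voxel_size_mm),
                 mask = ph$mask,
                 norm_value = ph$norm_value * acq$true_scale,
                 osem_init = voxel_image(x_init, spec$voxel_size_mm),
                 beta = beta, spec = spec),
            class = "benchmark_setup")
}

#' @export
print.benchmark_setup <- function(x, ...) {
  cat("<benchmark_setup> beta_tilde=", x$spec$beta_tilde,
      " (beta=", signif(x$beta, 4), "), ",
      format(x$spec$target_true_counts), " trues, ",
      x$bundle$n_subsets, " subsets\n", sep = "")
  invisible(x)
}

#' Reference for NRMSE tracking of a benchmark
#'
#' Runs the bound-constrained quasi-Newton reference solver on the
#' benchmark's objective and packages it with the phantom mask and
#' normalisation, in the form [run_algorithm()] expects.
#'
#' @param setup a [setup_benchmark()] result.
#' @param iterations quasi-Newton iteration budget (default 500).
#' @return list with `image`, `mask`, `norm_value` and `fit` (the full
#'   [reference_reconstruction()] result).
#' @export
benchmark_reference <- function(setup, iterations = 500) {
  fit <- reference_reconstruction(setup$bundle, iterations,
                                  x0 = img_values(setup$osem_init))
  list(image = fit$image, mask = setup$mask,
       norm_value = setup$norm_value, fit = fit)
}

#' Run a grid of reconstruction experiments
#'
#' Each row of `grid` describes one reconstruction cell; missing columns
#' fall back to the defaults of [recon_config()] and
#' [setup_benchmark()]. Recognised columns: `estimator`, `precond_kind`,
#' `stepsize_kind`, `tau0`, `eta`, `n_subsets`, `sampler`, `seed`,
#' `beta_tilde`, `target_trues`, `n_epochs`. Phantom data and the
#' converged reference are built once per unique
#' (`beta_tilde`, `target_trues`, `n_subsets`) combination and shared
#' across cells. Failing cells are recorded and do not stop the grid.
#'
#' @param grid data frame of cells.
#' @param spec base phantom spec (its `beta_tilde` / counts are
#'   overridden per cell where the grid provides them).
#' @param reference_iterations quasi-Newton budget for each reference.
#' @param n_epochs default epoch budget for cells without an `n_epochs`
#'   column.
#' @param objective_every objective logging cadence passed to
#'   [recon_config()]; `NULL` = once per epoch.
#' @param ... further arguments passed to [setup_benchmark()].
#' @return tibble with one row per cell: the cell parameters plus
#'   `updates_to_threshold`, `final_nrmse`, `n_updates`, `converged`,
#'   `diverged` and `error`.
#' @export
run_experiment_grid <- function(grid,
                                spec = default_phantom_spec(),
                                reference_iterations = 500,
                                n_epochs = 30,
                                objective_every = NULL, ...) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) stop("empty grid")
  setups <- new.env(parent = emptyenv())
  refs <- new.env(parent = emptyenv())
  col <- function(row, name, default) {
    if (name %in% names(row) && !is.na(row[[name]])) row[[name]]
    else default
  }
  results <- purrr::map(seq_len(nrow(grid)), function(ri) {
    row <- grid[ri, ]
    bt <- col(row, "beta_tilde", spec$beta_tilde)
    tc <- col(row, "target_trues", spec$target_true_counts)
    ns <- col(row, "n_subsets", NA)
    key <- paste(bt, tc, ns, sep = "|")
    out <- tryCatch({
      if (is.null(setups[[key]])) {
        sp <- spec
        sp$beta_tilde <- bt
        sp$target_true_counts <- tc
        setups[[key]] <- setup_benchmark(
          sp, n_subsets = if (is.na(ns)) NULL else as.integer(ns), ...)
      }
      su <- setups[[key]]
      rkey <- paste(bt, tc, sep = "|")
      if (is.null(refs[[rkey]]))
        refs[[rkey]] <- benchmark_reference(su, reference_iterations)
      ne <- as.integer(col(row, "n_epochs", n_epochs))
      cfg <- recon_config(
        estimator = col(row, "estimator", "svrg"),
        n_epochs = ne,
        stepsize_kind = col(row, "stepsize_kind", "vanishing"),
        tau0 = col(row, "tau0", 1), eta = col(row, "eta", 0.02),
        precond_kind = col(row, "precond_kind", "harmonic"),
        sampler = col(row, "sampler", "uniform_without"),
        seed = as.integer(col(row, "seed", 1L)),
        objective_every = if (is.null(objective_every))
          su$bundle$n_subsets else as.integer(objective_every))
      fit <- run_algorithm(su$bundle, cfg, reference = refs[[rkey]],
                           x0 = img_values(su$osem_init))
      tibble::tibble(
        updates_to_threshold = fit$updates_to_threshold,
        final_nrmse = utils::tail(fit$history$nrmse, 1),
        n_updates = nrow(fit$history),
        converged = fit$converged, diverged = fit$diverged,
        error = NA_character_)
    }, error = function(e) {
      tibble::tibble(updates_to_threshold = NA_integer_,
                     final_nrmse = NA_real_, n_updates = NA_integer_,
                     converged = NA, diverged = NA,
                     error = conditionMessage(e))
    })
    dplyr::bind_cols(row, out)
  })
  dplyr::bind_rows(results)
}
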