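#' Projected preconditioned gradient step
#'
#' `x <- max(0, x - tau * D * g)`: a gradient step scaled by the diagonal
#' preconditioner followed by projection onto the non-negative orthant
#' (an exact proximal step for the non-negativity constraint under any
#' positive diagonal metric).
#'
#' @param x current image array.
#' @param tau positive stepsize.
#' @param precond strictly positive diagonal preconditioner (image array).
#' @param grad gradient estimate (image array).
#' @return updated non-negative image array.
#' @export
prox_step <- function(x, tau, precond, grad) {
  if (tau <= 0) stop("tau must be positive")
  if (!all(is.finite(grad)))
    stop("non-finite gradient entries; reconstruction aborted")
  out <- x - tau * precond * grad
  out[out < 0] <- 0
  out
}

#' One or more epochs of ordered-subset expectation maximization
#'
#' The classic multiplicative OSEM update
#' `x <- (x / A_i'1) * A_i'(y_i / (A_i x + r_i))`, applied once per subset
#' in sequential order starting from a uniform positive image. Used to
#' initialise all stochastic reconstructions. Voxels with zero subset
#' sensitivity are left unchanged by that subset's update.
#'
#' @param bundle an [build_bundle()] object (the prior is ignored; OSEM
#'   is a pure maximum-likelihood method).
#' @param n_subsets number of OSEM subsets; default: the divisor of the
#'   view count closest to 27.
#' @param epochs number of full sweeps (default 1).
#' @param x0 optional positive starting image (default: all ones).
#' @return non-negative image array.
#' @export
osem_initialize <- function(bundle, n_subsets = NULL, epochs = 1,
                            x0 = NULL) {
  model <- bundle$model
  if (is.null(n_subsets))
    n_subsets <- choose_num_subsets(model$n_views, 27)
  part <- partition_views(model$n_views, n_subsets)
  rows <- lapply(part$view_lists,
                 function(v) which(model$view_of_row %in% v))
  y <- as.vector(bundle$data$counts)
  r <- as.vector(bundle$data$background)
  x <- if (is.null(x0)) array(1, dim = bundle$shape) else as.array(x0)
  if (any(x <= 0)) stop("OSEM requires a strictly positive start")
  for (ep in seq_len(epochs)) {
    for (s in seq_len(n_subsets)) {
      ri <- rows[[s]]
      Ai <- model$A[ri, , drop = FALSE]
      sens <- as.vector(Matrix::colSums(Ai))
      lam <- as.vector(Ai %*% as.vector(x)) + r[ri]
      bp <- as.vector(Matrix::t(Ai) %*% (y[ri] / lam))
      upd <- which(sens > 0)
      xv <- as.vector(x)
      xv[upd] <- xv[upd] / sens[upd] * bp[upd]
      x <- array(xv, dim = bundle$shape)
    }
  }
  x
}

#' Configuration for the stochastic reconstruction loop
#'
#' Collects every tunable of [run_algorithm()] with the package defaults.
#' The update counter `k` is 0-based and counts subset updates; an epoch
#' is `n_subsets` updates. Preconditioners are recomputed at the start of
#' the epochs in `precond_update_epochs` and frozen otherwise.
#' Barzilai-Borwein values (for `stepsize_kind = "capped_bb"`) are
#' computed from consecutive SVRG snapshots at the end of the epochs in
#' `bb_epochs`.
#'
#' @param estimator `"svrg"`, `"saga"` or `"sgd"`.
#' @param n_epochs maximum number of epochs.
#' @param stepsize_kind `"constant"`, `"vanishing"`, `"alg1_schedule"` or
#'   `"capped_bb"`.
#' @param tau0 initial stepsize (constant / vanishing rules).
#' @param eta decay of the vanishing rule.
#' @param precond_kind `"harmonic"` or `"mlem"`.
#' @param alpha prior-curvature weight of the harmonic preconditioner.
#' @param delta preconditioner floor; `NULL` = `1e-6 *` mean of the
#'   starting image (or 1 if that mean is 0).
#' @param precond_update_epochs epochs at whose start the preconditioner
#'   is recomputed.
#' @param sampler sampling strategy, see [new_sampler()].
#' @param seed integer seed for the subset sampler.
#' @param omega SVRG snapshot period in epochs (snapshots every
#'   `omega * n` updates, including `k = 0`).
#' @param svrg_variant `"memory"` or `"recompute"`.
#' @param bb_epochs epochs after which BB stepsizes are recomputed.
#' @param nrmse_threshold convergence threshold on NRMSE vs the reference.
#' @param stop_at_threshold stop as soon as the threshold is crossed?
#' @param objective_every log the full objective every this many updates
#'   (1 = every update; larger values trade logging density for speed).
#' @param osem_subsets,osem_epochs OSEM initialisation settings.
#' @return a list of class `recon_config`.
#' @export
recon_config <- function(estimator = "svrg",
                         n_epochs = 100,
                         stepsize_kind = "vanishing",
                         tau0 = 1, eta = 0.02,
                         precond_kind = "harmonic",
                         alpha = 1, delta = NULL,
                         precond_update_epochs = c(1, 2, 3),
                         sampler = "uniform_without",
                         seed = 1L,
                         omega = 2L,
                         svrg_variant = "memory",
                         bb_epochs = c(2, 4, 6),
                         nrmse_threshold = 0.01,
                         stop_at_threshold = TRUE,
                         objective_every = 1L,
                         osem_subsets = NULL,
                         osem_epochs = 1L) {
  cfg <- list(estimator = match.arg(estimator, c("svrg", "saga", "sgd")),
              n_epochs = as.integer(n_epochs),
              stepsize_kind = match.arg(stepsize_kind,
                c("vanishing", "constant", "alg1_schedule", "capped_bb")),
              tau0 = tau0, eta = eta,
              precond_kind = match.arg(precond_kind, c("harmonic", "mlem")),
              alpha = alpha, delta = delta,
              precond_update_epochs = as.integer(precond_update_epochs),
              sampler = sampler, seed = as.integer(seed),
              omega = as.integer(omega),
              svrg_variant = match.arg(svrg_variant,
                                       c("memory", "recompute")),
              bb_epochs = as.integer(bb_epochs),
              nrmse_threshold = nrmse_threshold,
              stop_at_threshold = isTRUE(stop_at_threshold),
              objective_every = as.integer(objective_every),
              osem_subsets = osem_subsets,
              osem_epochs = as.integer(osem_epochs))
  if (cfg$stepsize_kind == "capped_bb" && cfg$estimator != "svrg")
    stop("capped_bb stepsizes require the SVRG estimator ",
         "(BB values are computed at snapshot points)")
  class(cfg) <- "recon_config"
  cfg
}

#' Run the preconditioned proximal stochastic gradient loop
#'
#' Initialises with OSEM (unless `x0` is given), then iterates
#' `x <- max(0, x - tau(k) D(k) ghat(k))` with the configured gradient
#' estimator, preconditioner schedule, stepsize rule and subset sampler.
#' Logs stepsize, subset index, objective and (when a reference is
#' supplied) NRMSE per update. Aborts with a `diverged` flag if the
#' logged objective exceeds 10x its initial value.
#'
#' @param bundle an [build_bundle()] object.
#' @param config a [recon_config()].
#' @param reference optional reference for NRMSE tracking: a list with
#'   elements `image` (converged reference image), `mask` (logical
#'   array) and `norm_value` (positive scalar), as produced by
#'   [make_phantom()] / [reference_reconstruction()].
#' @param x0 optional starting image overriding the OSEM initialisation.
#' @return object of class `pet_recon`: list with the final `image`
#'   ([voxel_image()]), `history` (tibble with one row per update),
#'   `config`, `converged`, `diverged`, `updates_to_threshold` (`NA` if
#'   never reached) and the initial image `x0`.
#' @export
run_algorithm <- function(bundle, config = recon_config(),
                          reference = NULL, x0 = NULL) {
  stopifnot(inherits(bundle, "objective_bundle"),
            inherits(config, "recon_config"))
  n <- bundle$n_subsets
  if (is.null(x0))
    x0 <- osem_initialize(bundle, config$osem_subsets, config$osem_epochs)
  x <- as.array(x0)
  if (inherits(x0, "voxel_image")) x <- img_values(x0)

  delta <- config$delta
  if (is.null(delta)) {
    m <- mean(x)
    delta <- 1e-6 * if (m > 0) m else 1
  }
  sens <- array(bundle$model$sensitivity, dim = bundle$shape)
  compute_precond <- function(xc) {
    if (config$precond_kind == "mlem" || bundle$rdp$beta == 0)
      mlem_preconditioner(xc, sens, delta)
    else
      harmonic_preconditioner(xc, sens, bundle$rdp,
                              alpha = config$alpha, delta = delta)
  }

  smp <- new_sampler(config$sampler, n, seed = config$seed)
  est <- new_estimator(config$estimator, bundle, x,
                       svrg_variant = config$svrg_variant)
  if (config$sampler == "importance" && config$estimator == "svrg")
    sampler_set_probabilities(smp,
      importance_probabilities(est$subset_grad_list))

  bb_tau <- NA_real_
  prev_snap_x <- if (config$estimator == "svrg") est$snapshot else NULL
  prev_snap_g <- if (config$estimator == "svrg") est$full_grad else NULL

  stepsize_at <- function(k) {
    switch(config$stepsize_kind,
      constant = config$tau0,
      vanishing = vanishing_stepsize(k, config$tau0, config$eta, n),
      alg1_schedule = alg1_stepsize(k),
      capped_bb = capped_bb_stepsize(k, n, bb_tau))
  }

  nrmse_of <- function(xc) {
    if (is.null(reference)) return(NA_real_)
    nrmse(xc, reference$image, reference$mask, reference$norm_value)
  }

  J0 <- objective_value(x, bundle)
  K <- config$n_epochs * n
  hist_update <- integer(K); hist_epoch <- integer(K)
  hist_subset <- integer(K); hist_tau <- numeric(K)
  hist_obj <- rep(NA_real_, K); hist_nrmse <- rep(NA_real_, K)
  k <- 0L
  D <- NULL
  converged <- FALSE
  diverged <- FALSE
  updates_to_threshold <- NA_integer_

  for (epoch in seq_len(config$n_epochs)) {
    D <- preconditioner_schedule(epoch, config$precond_update_epochs, D,
                                 function() compute_precond(x))
    for (s in seq_len(n)) {
      if (config$estimator == "svrg" && k > 0L &&
          k %% (config$omega * n) == 0L) {
        svrg_snapshot_update(est, x, bundle)
        if (config$sampler == "importance")
          sampler_set_probabilities(smp,
            importance_probabilities(est$subset_grad_list))
        completed_epoch <- k %/% n
        if (config$stepsize_kind == "capped_bb" &&
            completed_epoch %in% config$bb_epochs) {
          tau_new <- bb_short_stepsize(est$snapshot - prev_snap_x,
                                       est$full_grad - prev_snap_g)
          if (!is.na(tau_new)) bb_tau <- tau_new
        }
        prev_snap_x <- est$snapshot
        prev_snap_g <- est$full_grad
      }
      i <- sampler_next(smp)
      g <- estimator_gradient(est, x, bundle, i)
      tau <- stepsize_at(k)
      x <- prox_step(x, tau, D, g)
      k <- k + 1L
      hist_update[k] <- k
      hist_epoch[k] <- epoch
      hist_subset[k] <- i
      hist_tau[k] <- tau
      hist_nrmse[k] <- nrmse_of(x)
      if (k %% config$objective_every == 0L) {
        hist_obj[k] <- objective_value(x, bundle)
        if (is.finite(J0) && hist_obj[k] > 10 * abs(J0) + 10) {
          diverged <- TRUE
          break
        }
      }
      if (!is.na(hist_nrmse[k]) &&
          hist_nrmse[k] < config$nrmse_threshold) {
        converged <- TRUE
        if (is.na(updates_to_threshold)) updates_to_threshold <- k
        if (config$stop_at_threshold) break
      }
    }
    if (diverged || (converged && config$stop_at_threshold)) break
  }

  keep <- seq_len(k)
  history <- tibble::tibble(
    update = hist_update[keep], epoch = hist_epoch[keep],
    subset = hist_subset[keep], stepsize = hist_tau[keep],
    objective = hist_obj[keep], nrmse = hist_nrmse[keep])
  structure(list(
    image = voxel_image(x, attr_voxel_size(bundle)),
    x0 = voxel_image(as.array(if (inherits(x0, "voxel_image"))
      img_values(x0) else x0), attr_voxel_size(bundle)),
    history = history, config = config,
    converged = converged, diverged = diverged,
    updates_to_threshold = updates_to_threshold,
    initial_objective = J0,
    n_subsets = n), class = "pet_recon")
}

attr_voxel_size <- function(bundle) bundle$model$voxel_size_mm

#' @export
print.pet_recon <- function(x, ...) {
  cat("<pet_recon> ", x$config$estimator, " + ", x$config$precond_kind,
      " preconditioner, ", x$n_subsets, " subsets, ",
      nrow(x$history), " updates; ",
      if (x$diverged) "DIVERGED"
      else if (x$converged) paste0("reached NRMSE threshold at update ",
                                   x$updates_to_threshold)
      else "threshold not reached", "\n", sep = "")
  invisible(x)
}

#' Bound-constrained quasi-Newton reference reconstruction
#'
#' Minimises the penalized objective `J(x)` subject to `x >= 0` with a
#' preconditioned limited-memory BFGS-B routine (via [stats::optim()])
#' for a fixed iteration budget. Used as the converged reference `x*`
#' for NRMSE tracking of the stochastic solvers.
#'
#' The prior's diagonal curvature spans many orders of magnitude between
#' active regions and near-zero background, which cripples an
#' unpreconditioned quasi-Newton method. The objective is therefore
#' minimised in rescaled variables `z = x / s` with
#' `s = 1 / sqrt(diag H(x))` (the diagonal curvature of the full smooth
#' objective), which leaves the non-negativity bound invariant and
#' equalises the diagonal curvature. Because the curvature changes as
#' background voxels reach the bound, the iteration budget is split into
#' a few restarts and the scaling is refreshed at each restart.
#'
#' @param bundle an [build_bundle()] object.
#' @param iterations total L-BFGS-B iteration budget (default 500).
#' @param x0 optional positive start (default: one epoch of OSEM).
#' @param precondition rescale variables by the diagonal curvature?
#'   (default `TRUE`).
#' @param restarts number of segments with refreshed scaling (default 4).
#' @return list of class `reference_recon` with `image`
#'   ([voxel_image()]), `converged` (logical; `optim` convergence code 0
#'   in the final segment), `optim_convergence` and `message`.
#' @export
reference_reconstruction <- function(bundle, iterations = 500, x0 = NULL,
                                     precondition = TRUE, restarts = 4) {
  if (is.null(x0)) x0 <- osem_initialize(bundle)
  shape <- bundle$shape
  nvox <- prod(shape)
  x <- as.vector(if (inherits(x0, "voxel_image")) img_values(x0) else x0)
  per_segment <- max(1L, as.integer(ceiling(iterations / restarts)))
  fit <- NULL
  for (seg in seq_len(restarts)) {
    s <- if (precondition) {
      xs <- pmax(x, 1e-12)  # scaling is evaluated at a feasible point
      h <- as.vector(data_diag_hessian(array(xs, dim = shape), bundle))
      if (bundle$rdp$beta > 0)
        h <- h + bundle$rdp$beta *
          as.vector(rdp_diag_hessian(array(xs, dim = shape), bundle$rdp))
      h <- pmax(h, 1e-12 * max(h))
      1 / sqrt(h)
    } else rep(1, nvox)
    fn <- function(z) {
      v <- s * z
      v[v < 0] <- 0
      objective_value(array(v, dim = shape), bundle)
    }
    gr <- function(z) {
      v <- s * z
      v[v < 0] <- 0
      s * as.vector(subset_gradient(array(v, dim = shape), bundle, NULL))
    }
    fit <- stats::optim(x / s, fn, gr, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = per_segment, factr = 10))
    x <- pmax(0, s * fit$par)
  }
  structure(list(
    image = voxel_image(array(x, dim = shape), attr_voxel_size(bundle)),
    converged = fit$convergence == 0,
    optim_convergence = fit$convergence,
    message = fit$message,
    value = fit$value), class = "reference_recon")
}

#' Diagonal of the data-fidelity Hessian
#'
#' `[A' diag(y / (Ax + r)^2) A]_jj`, the exact per-voxel curvature of the
#' Poisson data fidelity (used for reference-solver preconditioning and
#' curvature diagnostics).
#'
#' @param x image array.
#' @param bundle an [build_bundle()] object.
#' @return image array of non-negative curvatures.
#' @export
data_diag_hessian <- function(x, bundle) {
  xv <- as.vector(if (inherits(x, "voxel_image")) img_values(x) else x)
  yhat <- as.vector(bundle$model$A %*% xv) +
    as.vector(bundle$data$background)
  w <- as.vector(bundle$data$counts) / yhat^2
  array(as.vector(Matrix::colSums(bundle$model$A^2 * w)),
        dim = bundle$shape)
}

#' @export
print.reference_recon <- function(x, ...) {
  cat("<reference_recon> objective ", format(x$value),
      if (!x$converged) paste0(" (optim code ", x$optim_convergence, ")"),
      "\n", sep = "")
  invisible(x)
}
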