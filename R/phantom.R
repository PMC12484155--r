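#' Phantom specification and rasterisation
#'
#' `phantom_spec` describes a 2D ellipse phantom on a regular grid:
#' each ellipse has a centre and semi-axes in mm (grid centred at the
#' origin) and an activity level; later ellipses overwrite earlier ones
#' where they overlap, so hot and cold inserts are listed after the
#' background ellipse. `default_phantom_spec` is the package's desk-scale
#' study phantom: a 64 x 64 grid at 2.5 mm with a large elliptical
#' background, two hot inserts and one cold insert.
#'
#' `make_phantom` rasterises the spec and returns the activity image, the
#' support mask (union of all ellipses - the region over which NRMSE is
#' evaluated, excluding the cold surround) and the normalisation value:
#' the activity of the largest-area ellipse (the background ellipse).
#'
#' @param ellipses list of lists with elements `center` (length-2, mm),
#'   `semi_axes` (length-2, mm) and `activity` (>= 0).
#' @param shape integer image dimensions.
#' @param voxel_size_mm voxel size in mm.
#' @param target_true_counts expected total true coincidences for
#'   acquisition simulation.
#' @param beta_tilde relative regularisation strength (see
#'   [scale_beta()]).
#' @return `phantom_spec` returns a spec object; `make_phantom` a list
#'   with `image` ([voxel_image()]), `mask` (logical array) and
#'   `norm_value` (scalar).
#' @export
phantom_spec <- function(ellipses, shape = c(64L, 64L),
                         voxel_size_mm = 2.5,
                         target_true_counts = 3e5,
                         beta_tilde = 1) {
  if (length(ellipses) == 0L) stop("at least one ellipse is required")
  shape <- as.integer(shape)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 2L)
  half_fov <- shape * voxel_size_mm / 2
  for (e in ellipses) {
    if (e$activity < 0) stop("activities must be non-negative")
    if (any(abs(e$center) + e$semi_axes > half_fov))
      stop("ellipse extends beyond the grid")
  }
  if (target_true_counts <= 0) stop("target_true_counts must be positive")
  structure(list(ellipses = ellipses, shape = shape,
                 voxel_size_mm = voxel_size_mm,
                 target_true_counts = target_true_counts,
                 beta_tilde = beta_tilde),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_spec <- function(target_true_counts = 3e5,
                                 beta_tilde = 1) {
  phantom_spec(
    ellipses = list(
      list(center = c(0, 0), semi_axes = c(70, 55), activity = 1),
      list(center = c(30, 18), semi_axes = c(14, 14), activity = 3),
      list(center = c(-32, -12), semi_axes = c(10, 10), activity = 2),
      list(center = c(-5, 28), semi_axes = c(9, 9), activity = 0.25)),
    shape = c(64L, 64L), voxel_size_mm = 2.5,
    target_true_counts = target_true_counts, beta_tilde = beta_tilde)
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$shape[1]; ny <- spec$shape[2]
  vx <- spec$voxel_size_mm[1]; vy <- spec$voxel_size_mm[2]
  xc <- (seq_len(nx) - (nx + 1) / 2) * vx
  yc <- (seq_len(ny) - (ny + 1) / 2) * vy
  X <- matrix(rep(xc, times = ny), nx, ny)
  Y <- matrix(rep(yc, each = nx), nx, ny)
  img <- matrix(0, nx, ny)
  mask <- matrix(FALSE, nx, ny)
  for (e in spec$ellipses) {
    inside <- ((X - e$center[1]) / e$semi_axes[1])^2 +
      ((Y - e$center[2]) / e$semi_axes[2])^2 <= 1
    img[inside] <- e$activity
    mask <- mask | inside
  }
  areas <- vapply(spec$ellipses,
                  function(e) pi * prod(e$semi_axes), numeric(1))
  norm_value <- spec$ellipses[[which.max(areas)]]$activity
  list(image = voxel_image(img, spec$voxel_size_mm),
       mask = mask, norm_value = norm_value)
}

#' Simulate a Poisson acquisition
#'
#' Forward-projects the phantom, scales the noise-free sinogram so its
#' total equals `target_trues`, adds a smooth strictly positive
#' background (a heavily blurred copy of the true sinogram, rescaled so
#' that total background counts are
#' `background_fraction / (1 - background_fraction) * target_trues`),
#' and draws Poisson counts. The background is stored exactly (known
#' scatter/randoms expectation).
#'
#' @param phantom activity image ([voxel_image()] or array).
#' @param model a [build_projector()] forward model.
#' @param target_trues expected total true counts (> 0).
#' @param background_fraction background-to-total counts fraction in
#'   `[0, 1)`; a small positive floor keeps the background strictly
#'   positive even at 0.
#' @param seed integer seed for the Poisson draw (local RNG stream; the
#'   global RNG state is left untouched).
#' @return list of class `acquisition`: `sinogram` (a [sinogram()]),
#'   `true_scale` (factor by which the phantom's projection was scaled),
#'   `expected` (noise-free total expectation matrix) and
#'   `target_trues`.
#' @export
simulate_acquisition <- function(phantom, model, target_trues,
                                 background_fraction = 0.25, seed = 1L) {
  if (target_trues <= 0) stop("target_trues must be positive")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  trues <- forward_project(model, phantom)
  tot <- sum(trues)
  if (tot <= 0) stop("phantom has zero forward projection")
  true_scale <- target_trues / tot
  trues <- trues * true_scale

  Bv <- as.matrix(blur_matrix_1d(model$n_views, model$n_views / 2))
  Br <- as.matrix(blur_matrix_1d(model$n_radial, model$n_radial / 2))
  bg <- Bv %*% trues %*% t(Br)
  bg_target <- background_fraction / (1 - background_fraction) *
    target_trues
  bg <- if (bg_target > 0 && sum(bg) > 0) bg * bg_target / sum(bg)
        else 0 * bg
  floor_val <- 1e-6 * target_trues / length(bg)
  bg <- pmax(bg, floor_val)

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  counts <- matrix(stats::rpois(length(trues), as.vector(trues + bg)),
                   model$n_views, model$n_radial)
  restore_rng(old)

  structure(list(sinogram = sinogram(counts, bg),
                 true_scale = true_scale,
                 expected = trues + bg,
                 target_trues = target_trues),
            class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  cat("<acquisition> ", sum(x$sinogram$counts), " counts (target trues ",
      format(x$target_trues), ", scale ", signif(x$true_scale, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Count-level scaling of the regularisation parameter
#'
#' `beta = beta_tilde * 2e-4 * true_counts / 3e7`, so reconstructions
#' with the same relative strength `beta_tilde` at different count levels
#' have comparable resolution.
#'
#' @param beta_tilde relative regularisation strength (> 0).
#' @param true_counts expected total true coincidences (> 0).
#' @return the absolute regularisation weight `beta`.
#' @export
scale_beta <- function(beta_tilde, true_counts) {
  if (beta_tilde <= 0 || true_counts <= 0)
    stop("beta_tilde and true_counts must be positive")
  beta_tilde * 2e-4 * true_counts / 3e7
}

#' Normalised root mean square error over a mask
#'
#' `sqrt(mean((x - reference)^2 over mask)) / norm_value`. The mask
#' excludes the cold surround of the phantom; the normalisation is the
#' activity of the largest background ellipse.
#'
#' @param x,reference image arrays of identical shape.
#' @param mask logical array selecting the voxels to compare.
#' @param norm_value positive normalisation intensity.
#' @return scalar NRMSE.
#' @export
nrmse <- function(x, reference, mask, norm_value) {
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  ra <- if (inherits(reference, "voxel_image")) img_values(reference)
        else as.array(reference)
  if (!identical(dim(xa), dim(ra))) stop("shapes must match")
  if (norm_value <= 0) stop("norm_value must be positive")
  if (!any(mask)) stop("mask must select at least one voxel")
  sqrt(mean((xa[mask] - ra[mask])^2)) / norm_value
}

#' Perturbation-response weight factors for the prior
#'
#' The field-standard surrogate `kappa_j = sqrt([A' diag(y / yhat^2) A 1]_j)`
#' evaluated at an image estimate `x` (with `yhat = A x + r`): the square
#' root of the row sums of the data-fidelity Hessian. Using these as the
#' per-voxel `kappa` in [rdp_params()] matches the local curvature of the
#' prior to that of the likelihood, which makes a given `beta` act with
#' comparable relative strength across geometries and count levels.
#' Entries are floored at `1e-6` times the maximum so that `kappa` stays
#' strictly positive outside the scanner's sensitive region.
#'
#' @param model a [build_projector()] forward model.
#' @param data a [sinogram()].
#' @param x image estimate at which to evaluate the curvature (e.g. the
#'   OSEM initialisation).
#' @return positive image array of weight factors.
#' @export
kappa_perturbation <- function(model, data, x) {
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  yhat <- as.vector(model$A %*% as.vector(xa)) +
    as.vector(data$background)
  w <- as.vector(data$counts) / yhat^2
  row_mass <- as.vector(model$A %*% rep(1, length(xa)))
  k2 <- as.vector(model$At %*% (w * row_mass))
  k <- sqrt(pmax(k2, 0))
  k <- pmax(k, 1e-6 * max(k))
  array(k, dim = dim(xa))
}
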