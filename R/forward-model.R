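#' Build a desk-scale parallel-beam tomographic forward model
#'
#' Constructs the linear operator `A = P G B` as an explicit sparse matrix:
#' `B` is an optional Gaussian image-space blur modelling limited spatial
#' resolution, `G` a pixel-driven parallel-beam projector with equally
#' spaced view angles in `[0, pi)`, and `P` a diagonal of per-bin
#' attenuation factors `exp(-line integral of mu)` when an attenuation map
#' is supplied. The explicit matrix makes the adjoint exact (the
#' transpose), which keeps subset restrictions and brute-force oracles
#' trivial.
#'
#' Radial bins are spaced by the (smallest) voxel size and are symmetric
#' about the grid centre; projected voxel mass is linearly interpolated
#' between the two nearest radial bins and scaled so that each bin value
#' approximates a line integral in `value * mm`.
#'
#' @param image_shape integer vector of length 2 (2D grids).
#' @param voxel_size_mm positive voxel size in mm (scalar or per-axis).
#' @param n_views number of view angles (>= 1), equally spaced in `[0, pi)`.
#' @param n_radial number of radial bins.
#' @param psf_fwhm_mm full width at half maximum of the isotropic Gaussian
#'   image-space resolution model, in mm; 0 disables the blur.
#' @param attenuation_image optional [voxel_image()] of linear attenuation
#'   coefficients (1/mm); when supplied, per-bin attenuation factors are
#'   applied multiplicatively.
#' @return An object of class `forward_model` with the sparse system matrix,
#'   its transpose, the sensitivity image `A' 1`, and the geometry metadata.
#' @export
build_projector <- function(image_shape, voxel_size_mm, n_views, n_radial,
                            psf_fwhm_mm = 0, attenuation_image = NULL) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L) stop("image_shape must have length 2")
  if (any(image_shape <= 0L)) stop("image dimensions must be positive")
  if (n_views < 1L) stop("n_views must be >= 1")
  if (n_radial < 1L) stop("n_radial must be >= 1")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be non-negative")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 2L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")

  nx <- image_shape[1]; ny <- image_shape[2]
  vx <- voxel_size_mm[1]; vy <- voxel_size_mm[2]
  dr <- min(voxel_size_mm)
  n_bins <- n_views * n_radial

  # voxel centre coordinates (mm), grid centred at the origin
  xc <- (seq_len(nx) - (nx + 1) / 2) * vx
  yc <- (seq_len(ny) - (ny + 1) / 2) * vy
  X <- rep(xc, times = ny)
  Y <- rep(yc, each = nx)
  nvox <- nx * ny
  scale <- vx * vy / dr  # strip integral normalisation: value * mm per bin

  angles <- (seq_len(n_views) - 1) * pi / n_views
  rows <- vector("list", n_views)
  cols <- vector("list", n_views)
  vals <- vector("list", n_views)
  half <- (n_radial + 1) / 2
  for (v in seq_len(n_views)) {
    t_mm <- X * cos(angles[v]) + Y * sin(angles[v])
    u <- t_mm / dr + half           # fractional radial bin (1-based)
    i0 <- floor(u)
    frac <- u - i0
    # two interpolation targets per voxel
    bin <- c(i0, i0 + 1)
    w <- c(1 - frac, frac) * scale
    voxel <- c(seq_len(nvox), seq_len(nvox))
    keep <- bin >= 1 & bin <= n_radial & w > 0
    # sinogram linear index: view-major rows, dim (n_views, n_radial)
    rows[[v]] <- v + n_views * (bin[keep] - 1)
    cols[[v]] <- voxel[keep]
    vals[[v]] <- w[keep]
  }
  G <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(n_bins, nvox))

  B <- NULL
  if (psf_fwhm_mm > 0) {
    Bx <- blur_matrix_1d(nx, psf_fwhm_mm / vx)
    By <- blur_matrix_1d(ny, psf_fwhm_mm / vy)
    B <- Matrix::kronecker(By, Bx)   # acts on vec(image[x, y])
  }

  atten <- NULL
  if (!is.null(attenuation_image)) {
    mu <- as.vector(img_values(attenuation_image))
    if (length(mu) != nvox) stop("attenuation image shape mismatch")
    atten <- as.vector(exp(-(G %*% mu)))
  }

  A <- G
  if (!is.null(B)) A <- A %*% B
  if (!is.null(atten)) A <- Matrix::Diagonal(x = atten) %*% A
  A <- Matrix::drop0(A)

  sensitivity <- as.vector(Matrix::colSums(A))
  if (any(sensitivity <= 0))
    warning("sensitivity A'1 has non-positive entries; ",
            "increase n_radial to cover the grid")

  structure(list(
    A = A, At = Matrix::t(A),
    image_shape = image_shape, voxel_size_mm = voxel_size_mm,
    n_views = as.integer(n_views), n_radial = as.integer(n_radial),
    radial_spacing_mm = dr, psf_fwhm_mm = psf_fwhm_mm,
    attenuation = atten,
    view_of_row = rep(seq_len(n_views) - 1L, times = n_radial),
    sensitivity = sensitivity
  ), class = "forward_model")
}

# 1D truncated, column-normalised Gaussian convolution matrix
blur_matrix_1d <- function(n, sigma_voxels) {
  sigma <- sigma_voxels / (2 * sqrt(2 * log(2)))  # FWHM -> sigma
  if (sigma <= 0) return(Matrix::Diagonal(n))
  r <- max(1L, ceiling(3 * sigma))
  i <- rep(seq_len(n), each = 2 * r + 1)
  j <- i + rep(-r:r, times = n)
  keep <- j >= 1 & j <= n
  i <- i[keep]; j <- j[keep]
  w <- exp(-((i - j)^2) / (2 * sigma^2))
  M <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  # normalise columns: each voxel's spread mass sums to one
  cs <- Matrix::colSums(M)
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' @export
print.forward_model <- function(x, ...) {
  cat("<forward_model> ", paste(x$image_shape, collapse = " x "),
      " voxels -> ", x$n_views, " views x ", x$n_radial, " radial bins; ",
      "psf ", x$psf_fwhm_mm, " mm; ",
      if (is.null(x$attenuation)) "no attenuation" else "attenuated",
      "\n", sep = "")
  invisible(x)
}

#' Apply a forward model or its adjoint
#'
#' @param model a [build_projector()] result.
#' @param x image array (or vector) to project / sinogram matrix (or vector)
#'   to back-project.
#' @param views optional 0-based view indices restricting the operator to a
#'   subset of views (the row restriction `A_i`).
#' @return `forward_project` returns an `n_views x n_radial` matrix (rows of
#'   excluded views are zero when `views` is given); `back_project` returns
#'   an image array.
#' @export
forward_project <- function(model, x, views = NULL) {
  xv <- as.vector(if (inherits(x, "voxel_image")) img_values(x) else x)
  if (is.null(views)) {
    s <- as.vector(model$A %*% xv)
  } else {
    rows <- which(model$view_of_row %in% views)
    s <- numeric(model$n_views * model$n_radial)
    s[rows] <- as.vector(model$A[rows, , drop = FALSE] %*% xv)
  }
  matrix(s, model$n_views, model$n_radial)
}

#' @rdname forward_project
#' @export
back_project <- function(model, x, views = NULL) {
  sv <- as.vector(x)
  if (is.null(views)) {
    b <- as.vector(model$At %*% sv)
  } else {
    rows <- which(model$view_of_row %in% views)
    b <- as.vector(model$At[, rows, drop = FALSE] %*% sv[rows])
  }
  array(b, dim = model$image_shape)
}

#' Sensitivity image of a view subset
#'
#' `A_i' 1` for the rows belonging to the given views; with `views = NULL`
#' the full sensitivity `A' 1`.
#'
#' @inheritParams forward_project
#' @return image array.
#' @export
subset_sensitivity <- function(model, views = NULL) {
  if (is.null(views)) return(array(model$sensitivity,
                                   dim = model$image_shape))
  rows <- which(model$view_of_row %in% views)
  array(as.vector(Matrix::colSums(model$A[rows, , drop = FALSE])),
        dim = model$image_shape)
}
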