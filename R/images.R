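#' Voxel image container
#'
#' A light wrapper around a numeric array (2D or 3D) holding a non-negative
#' activity distribution on a regular grid, together with the physical voxel
#' size in millimetres.
#'
#' @param values numeric array (2D or 3D) of activity values; all finite.
#' @param voxel_size_mm positive numeric, one value per axis (recycled if
#'   scalar).
#' @return An object of class `voxel_image`: the array with a
#'   `voxel_size_mm` attribute.
#' @export
voxel_image <- function(values, voxel_size_mm = 1) {
  values <- as.array(values)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("voxel_image must be 2D or 3D")
  if (!all(is.finite(values))) stop("voxel_image values must be finite")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), nd)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  structure(values, voxel_size_mm = voxel_size_mm, class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat("<voxel_image> ", paste(dim(x), collapse = " x "),
      " voxels, ", paste(attr(x, "voxel_size_mm"), collapse = " x "),
      " mm, range [", signif(min(x), 4), ", ", signif(max(x), 4), "]\n",
      sep = "")
  invisible(x)
}

img_values <- function(x) {
  v <- unclass(x)
  attr(v, "voxel_size_mm") <- NULL
  v
}

#' Sinogram container
#'
#' View-binned projection data: Poisson counts and the known strictly
#' positive additive background expectation (scatter and randoms), both
#' indexed (view, radial bin).
#'
#' @param counts non-negative numeric matrix, `n_views x n_radial`.
#' @param background strictly positive numeric matrix, same shape.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(counts, background) {
  counts <- as.matrix(counts)
  background <- as.matrix(background)
  if (!identical(dim(counts), dim(background)))
    stop("counts and background must have identical shapes")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(background <= 0)) stop("background must be strictly positive")
  structure(list(counts = counts, background = background,
                 n_views = nrow(counts), n_radial = ncol(counts)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat("<sinogram> ", x$n_views, " views x ", x$n_radial,
      " radial bins, total counts ", format(sum(x$counts)), "\n", sep = "")
  invisible(x)
}

#' Read and write voxel images as NIfTI
#'
#' The voxel size is carried in the NIfTI header (pixdim).
#'
#' @param image a [voxel_image()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_image_nifti` returns `path` invisibly; `read_image_nifti`
#'   returns a [voxel_image()].
#' @export
write_image_nifti <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  img <- RNifti::asNifti(img_values(image))
  RNifti::pixdim(img) <- attr(image, "voxel_size_mm")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_size_mm <- RNifti::pixdim(img)[seq_along(dim(img))]
  arr <- array(as.vector(as.array(img)), dim = dim(img))
  voxel_image(arr, voxel_size_mm)
}

#' Read and write sinograms as plain-text CSV
#'
#' Long format with columns `view`, `radial`, `counts`, `background`
#' (0-based indices), so files are diffable and portable.
#'
#' @param sino a [sinogram()].
#' @param path file path.
#' @return `write_sinogram_csv` returns `path` invisibly;
#'   `read_sinogram_csv` returns a [sinogram()].
#' @export
write_sinogram_csv <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  idx <- expand.grid(view = seq_len(sino$n_views) - 1L,
                     radial = seq_len(sino$n_radial) - 1L)
  df <- data.frame(idx, counts = as.vector(sino$counts),
                   background = as.vector(sino$background))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram_csv
#' @export
read_sinogram_csv <- function(path) {
  df <- read.csv(path)
  n_views <- max(df$view) + 1L
  n_radial <- max(df$radial) + 1L
  counts <- matrix(0, n_views, n_radial)
  background <- matrix(0, n_views, n_radial)
  i <- cbind(df$view + 1L, df$radial + 1L)
  counts[i] <- df$counts
  background[i] <- df$background
  sinogram(counts, background)
}
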