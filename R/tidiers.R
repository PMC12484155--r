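#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-update history of a reconstruction
#'
#' @param x a [run_algorithm()] result.
#' @param ... unused.
#' @return tibble with columns `update`, `epoch`, `subset`, `stepsize`,
#'   `objective` and `nrmse`.
#' @export
tidy.pet_recon <- function(x, ...) {
  x$history
}

#' One-row summary of a reconstruction
#'
#' @param x a [run_algorithm()] result.
#' @param ... unused.
#' @return one-row tibble: estimator, preconditioner, subset count,
#'   updates run, first update at which the NRMSE threshold was crossed
#'   (`NA` if never), final NRMSE and objective, convergence and
#'   divergence flags.
#' @export
glance.pet_recon <- function(x, ...) {
  h <- x$history
  last_obj <- rev(h$objective[!is.na(h$objective)])
  tibble::tibble(
    estimator = x$config$estimator,
    preconditioner = x$config$precond_kind,
    n_subsets = x$n_subsets,
    n_updates = nrow(h),
    updates_to_threshold = x$updates_to_threshold,
    final_nrmse = utils::tail(h$nrmse, 1),
    final_objective = if (length(last_obj)) last_obj[1] else NA_real_,
    converged = x$converged,
    diverged = x$diverged)
}

#' Convergence plot of a reconstruction
#'
#' NRMSE against subset updates on log-log axes, with the convergence
#' threshold drawn as a horizontal line.
#'
#' @param object a [run_algorithm()] result (with a reference, so that
#'   NRMSE was tracked).
#' @param threshold threshold line to draw (default: the run's
#'   configured threshold).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pet_recon <- function(object, threshold = NULL, ...) {
  h <- dplyr::filter(object$history, !is.na(.data$nrmse))
  if (nrow(h) == 0L)
    stop("no NRMSE history; run with a reference to plot convergence")
  if (is.null(threshold)) threshold <- object$config$nrmse_threshold
  ggplot2::ggplot(h, ggplot2::aes(x = .data$update, y = .data$nrmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linewidth = 1,
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "subset updates", y = "NRMSE vs reference") +
    ggplot2::theme_minimal()
}

#' Plot an image slice
#'
#' @param object a [voxel_image()] (2D).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.voxel_image <- function(object, ...) {
  v <- img_values(object)
  if (length(dim(v)) != 2L) stop("autoplot supports 2D images")
  df <- expand.grid(x = seq_len(nrow(v)), y = seq_len(ncol(v)))
  df$value <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_void()
}

#' Convergence comparison plot for an experiment grid
#'
#' Updates-to-threshold per cell, grouped by estimator and
#' preconditioner.
#'
#' @param results a [run_experiment_grid()] tibble.
#' @return a ggplot object.
#' @export
plot_grid_results <- function(results) {
  df <- dplyr::mutate(results,
    cell = paste(.data$estimator, .data$precond_kind, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell,
                                   y = .data$updates_to_threshold)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "updates to NRMSE threshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
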