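#' Stochastic gradient estimators
#'
#' `new_estimator` creates the state for one of the three estimators of
#' the full objective gradient used inside the reconstruction loop:
#'
#' * `"sgd"`: `n * grad J_i(x)` - unbiased but with variance that grows
#'   with the number of subsets; no state.
#' * `"saga"`: keeps a table of the last gradient seen for every subset;
#'   the estimator is `n (grad J_i(x) - g_i) + sum_j g_j`, after which
#'   the table entry `i` is overwritten with the fresh gradient. The
#'   table is initialised with the subset gradients at the starting
#'   image, so the very first estimator equals the full gradient.
#' * `"svrg"`: keeps a snapshot image and its subset gradients, refreshed
#'   every `omega * n` updates; the estimator is
#'   `n (grad J_i(x) - ghat_i) + ghat`. The `"memory"` variant stores all
#'   snapshot subset gradients; the `"recompute"` variant stores only the
#'   snapshot image and full gradient and recomputes `ghat_i` on demand -
#'   both produce bit-identical estimators.
#'
#' @param kind `"sgd"`, `"saga"` or `"svrg"`.
#' @param bundle an [build_bundle()] object.
#' @param x0 starting image (used to fill the SAGA table / first SVRG
#'   snapshot).
#' @param svrg_variant `"memory"` or `"recompute"`.
#' @return an estimator state (environment) of class `grad_estimator`.
#' @export
new_estimator <- function(kind = c("svrg", "saga", "sgd"), bundle, x0,
                          svrg_variant = c("memory", "recompute")) {
  kind <- match.arg(kind)
  svrg_variant <- match.arg(svrg_variant)
  st <- new.env(parent = emptyenv())
  st$kind <- kind
  st$n <- bundle$n_subsets
  st$variant <- svrg_variant
  if (kind == "saga") {
    grads <- lapply(seq_len(st$n) - 1L,
                    function(i) as.vector(subset_gradient(x0, bundle, i)))
    st$table <- do.call(cbind, grads)
    st$table_sum <- rowSums(st$table)
  } else if (kind == "svrg") {
    svrg_snapshot_update(st, x0, bundle)
  }
  class(st) <- "grad_estimator"
  st
}

#' @export
print.grad_estimator <- function(x, ...) {
  cat("<grad_estimator> ", x$kind,
      if (x$kind == "svrg") paste0(" (", x$variant, ")"), "\n", sep = "")
  invisible(x)
}

#' Refresh the SVRG snapshot
#'
#' Sets the snapshot image to `x` and recomputes the per-subset gradients
#' `ghat_i = grad J_i(x)` and their sum `ghat` (the full gradient at the
#' snapshot). Call every `omega * n` updates, including at `k = 0`.
#'
#' @param st an SVRG estimator state.
#' @param x current image.
#' @param bundle an [build_bundle()] object.
#' @return the state, invisibly; `st$full_grad` then holds `ghat`.
#' @export
svrg_snapshot_update <- function(st, x, bundle) {
  if (!is.null(st$kind) && st$kind != "svrg")
    stop("snapshot updates only apply to SVRG")
  xa <- if (inherits(x, "voxel_image")) img_values(x) else as.array(x)
  st$snapshot <- xa
  grads <- lapply(seq_len(bundle$n_subsets) - 1L,
                  function(i) as.vector(subset_gradient(xa, bundle, i)))
  st$full_grad <- Reduce(`+`, grads)
  st$snapshot_grads <- if (identical(st$variant, "recompute")) NULL
                       else do.call(cbind, grads)
  st$subset_grad_list <- grads  # kept transiently for importance sampling
  invisible(st)
}

#' Evaluate a gradient estimator at the current iterate
#'
#' Returns the estimator of the full gradient for subset draw `i` and,
#' for SAGA, performs the table update as a side effect.
#'
#' @param st estimator state from [new_estimator()].
#' @param x current image array.
#' @param bundle an [build_bundle()] object.
#' @param i 0-based subset index.
#' @return gradient estimate as an image array.
#' @export
estimator_gradient <- function(st, x, bundle, i) {
  n <- bundle$n_subsets
  gi <- as.vector(subset_gradient(x, bundle, i))
  est <- switch(st$kind,
    sgd = n * gi,
    saga = {
      old <- st$table[, i + 1L]
      out <- n * (gi - old) + st$table_sum
      st$table[, i + 1L] <- gi
      st$table_sum <- st$table_sum + (gi - old)
      out
    },
    svrg = {
      if (is.null(st$snapshot)) stop("SVRG snapshot missing")
      ghat_i <- if (is.null(st$snapshot_grads))
        as.vector(subset_gradient(st$snapshot, bundle, i))
      else st$snapshot_grads[, i + 1L]
      n * (gi - ghat_i) + st$full_grad
    })
  array(est, dim = bundle$shape)
}
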