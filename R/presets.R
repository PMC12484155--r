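#' Algorithm presets ALG1 / ALG2 / ALG3
#'
#' The three tuned configurations of the stochastic reconstruction loop.
#' All use SVRG with the harmonic-mean preconditioner; they differ in
#' preconditioner update epochs, subset-count target, subset ordering
#' and stepsize rule:
#'
#' * `ALG1`: preconditioner updates at epochs 1, 2, 3; subset count =
#'   divisor of the view count closest to 25; a fixed random
#'   without-replacement sequence; the fixed piecewise stepsize schedule
#'   ([alg1_stepsize()]).
#' * `ALG2`: preconditioner updates at epochs 1, 2, 4, 6; same subsets
#'   and sampler as ALG1; capped Barzilai-Borwein stepsizes
#'   ([capped_bb_stepsize()]) with BB values computed at the end of
#'   epochs 2, 4 and 6.
#' * `ALG3`: as ALG2 but with subset target 24.2 and the cofactor
#'   ordering.
#'
#' @param name `"ALG1"`, `"ALG2"` or `"ALG3"`.
#' @return list of class `algorithm_preset` with fields `name`,
#'   `estimator`, `precond_kind`, `precond_update_epochs`,
#'   `subset_target`, `sampler`, `stepsize_kind` and `bb_epochs`.
#' @export
load_preset <- function(name) {
  presets <- c("ALG1", "ALG2", "ALG3")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; valid names: ",
         paste(presets, collapse = ", "))
  p <- switch(name,
    ALG1 = list(precond_update_epochs = c(1, 2, 3), subset_target = 25,
                sampler = "fixed_without",
                stepsize_kind = "alg1_schedule"),
    ALG2 = list(precond_update_epochs = c(1, 2, 4, 6), subset_target = 25,
                sampler = "fixed_without", stepsize_kind = "capped_bb"),
    ALG3 = list(precond_update_epochs = c(1, 2, 4, 6),
                subset_target = 24.2, sampler = "cofactor",
                stepsize_kind = "capped_bb"))
  structure(c(list(name = name, estimator = "svrg",
                   precond_kind = "harmonic", bb_epochs = c(2, 4, 6)),
              p), class = "algorithm_preset")
}

#' @export
print.algorithm_preset <- function(x, ...) {
  cat("<algorithm_preset> ", x$name, ": ", x$estimator, " + ",
      x$precond_kind, " PC (epochs ",
      paste(x$precond_update_epochs, collapse = ","), "), subsets ~",
      x$subset_target, ", ", x$sampler, " sampling, ",
      x$stepsize_kind, " stepsizes\n", sep = "")
  invisible(x)
}

#' Turn a preset into a runnable configuration
#'
#' @param preset a [load_preset()] result.
#' @param n_views view count of the data (to resolve the subset target
#'   into an actual divisor).
#' @param seed sampler seed.
#' @param ... overrides passed on to [recon_config()] (e.g. `n_epochs`).
#' @return list with `config` (a [recon_config()]) and `n_subsets`.
#' @export
preset_config <- function(preset, n_views, seed = 1L, ...) {
  stopifnot(inherits(preset, "algorithm_preset"))
  n_subsets <- choose_num_subsets(n_views, preset$subset_target)
  cfg <- recon_config(
    estimator = preset$estimator,
    precond_kind = preset$precond_kind,
    precond_update_epochs = preset$precond_update_epochs,
    sampler = preset$sampler,
    stepsize_kind = preset$stepsize_kind,
    bb_epochs = preset$bb_epochs,
    seed = seed, ...)
  list(config = cfg, n_subsets = n_subsets)
}

#' Read and write run configurations as YAML
#'
#' A configuration file is a flat mapping of [recon_config()] fields
#' (plus optional `preset`, `beta_tilde`, `target_trues`, `n_views`,
#' `n_radial` keys used by the command-line driver).
#'
#' @param config a named list (e.g. a [recon_config()]).
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` a named
#'   list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a JSON run manifest
#'
#' Records every resolved hyperparameter and seed of a finished
#' reconstruction so the run can be reproduced bit-exactly.
#'
#' @param fit a [run_algorithm()] result.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
run_manifest <- function(fit, path) {
  stopifnot(inherits(fit, "pet_recon"))
  manifest <- list(
    config = unclass(fit$config),
    n_subsets = fit$n_subsets,
    n_updates = nrow(fit$history),
    converged = fit$converged,
    diverged = fit$diverged,
    updates_to_threshold = fit$updates_to_threshold,
    initial_objective = fit$initial_objective,
    package_version = as.character(utils::packageVersion("petrdp")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
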