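#' Partition views into interleaved subsets
#'
#' Subset `i` (0-based) contains exactly the views congruent to `i` modulo
#' `n_subsets`, i.e. the data are divided by selecting every n-th view,
#' which keeps the angular coverage of each subset uniform.
#'
#' @param n_views total number of views.
#' @param n_subsets number of subsets, `1 <= n_subsets <= n_views`.
#' @return An object of class `subset_partition`: list with `n_subsets`,
#'   `n_views` and `view_lists` (a list of 0-based view index vectors).
#' @export
partition_views <- function(n_views, n_subsets) {
  n_views <- as.integer(n_views); n_subsets <- as.integer(n_subsets)
  if (n_subsets < 1L) stop("n_subsets must be >= 1")
  if (n_subsets > n_views) stop("n_subsets must not exceed n_views")
  view_lists <- lapply(seq_len(n_subsets) - 1L,
                       function(i) seq.int(i, n_views - 1L, by = n_subsets))
  structure(list(n_subsets = n_subsets, n_views = n_views,
                 view_lists = view_lists),
            class = "subset_partition")
}

#' @export
print.subset_partition <- function(x, ...) {
  cat("<subset_partition> ", x$n_views, " views in ", x$n_subsets,
      " interleaved subsets\n", sep = "")
  invisible(x)
}

#' Choose a subset count close to a target
#'
#' Returns the divisor of `n_views` closest to `target` (so the views
#' partition evenly); ties are broken toward the smaller divisor.
#'
#' @param n_views total number of views.
#' @param target positive target subset count (e.g. 25 or 24.2).
#' @return integer divisor of `n_views`.
#' @export
choose_num_subsets <- function(n_views, target) {
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("n_views must be >= 1")
  if (target <= 0) stop("target must be positive")
  divs <- which(n_views %% seq_len(n_views) == 0L)
  d <- abs(divs - target)
  # order() is stable: among equal distances the smaller divisor wins
  divs[order(d)][1L]
}
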