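#' Herman-Meyer subset order
#'
#' Deterministic access order built from the prime decomposition of `n`,
#' designed to maximise the angular information gain between successive
#' subset updates. Factors are taken in ascending order; each stage
#' distributes indices across the residue classes of its factor.
#'
#' @param n number of subsets (>= 1).
#' @return integer vector: a permutation of `0:(n-1)`.
#' @export
herman_meyer_order <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) return(0L)
  factors <- prime_factors(n)
  nf <- length(factors)
  order <- integer(n)
  value <- 0L
  for (fi in seq_len(nf)) {
    n_change <- if (fi == 1L) 1L else prod(factors[seq_len(fi - 1L)])
    mult <- if (fi == nf) 1L else prod(factors[seq.int(fi + 1L, nf)])
    n_rep <- 0L
    for (el in seq_len(n)) {
      mapping <- value
      n_rep <- n_rep + 1L
      if (n_rep >= n_change) {
        value <- value + 1L
        n_rep <- 0L
      }
      if (value == factors[fi]) value <- 0L
      order[el] <- order[el] + mult * mapping
    }
  }
  as.integer(order)
}

prime_factors <- function(n) {
  out <- integer(0)
  d <- 2L
  while (d * d <= n) {
    while (n %% d == 0L) {
      out <- c(out, d)
      n <- n %/% d
    }
    d <- d + 1L
  }
  if (n > 1L) out <- c(out, n)
  out
}

#' Cofactor subset ordering: ranked generators and traversals
#'
#' `cofactor_generators(n)` lists the generators of the cyclic group
#' Z/nZ - the integers `1 < k < n` coprime with `n` (the trivial
#' generator 1 is excluded) - ranked by proximity to the two reference
#' points `0.3 n` and `0.7 n`: generators are assigned to their nearer
#' reference point, each part is sorted by distance (ties toward the
#' smaller integer), and the two parts are interleaved starting with the
#' `0.3 n` part. The ranking balances angular spread against variety
#' across epochs.
#'
#' `cofactor_traversal(n, g)` is one epoch's subset sequence under
#' generator `g`: `(0, g, 2g, ...) mod n`, a full cover of `0:(n-1)`
#' whenever `gcd(g, n) = 1`.
#'
#' @param n number of subsets (>= 2 for generators to exist).
#' @param g a generator coprime with `n`.
#' @return integer vectors (0-based subset indices / generators).
#' @export
cofactor_generators <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  k <- seq.int(2L, max(2L, n - 1L))
  k <- k[k < n & vapply(k, function(x) gcd(x, n) == 1L, logical(1))]
  if (length(k) == 0L) return(integer(0))
  ref <- c(0.3 * n, 0.7 * n)
  d1 <- abs(k - ref[1]); d2 <- abs(k - ref[2])
  part1 <- k[d1 <= d2]; part2 <- k[d1 > d2]
  part1 <- part1[order(abs(part1 - ref[1]), part1)]
  part2 <- part2[order(abs(part2 - ref[2]), part2)]
  interleave(part1, part2)
}

gcd <- function(a, b) {
  while (b != 0L) {
    t <- b; b <- a %% b; a <- t
  }
  a
}

interleave <- function(a, b) {
  m <- max(length(a), length(b))
  out <- integer(0)
  for (i in seq_len(m)) {
    if (i <= length(a)) out <- c(out, a[i])
    if (i <= length(b)) out <- c(out, b[i])
  }
  out
}

#' @rdname cofactor_generators
#' @export
cofactor_traversal <- function(n, g) {
  n <- as.integer(n)
  if (gcd(as.integer(g) %% n, n) != 1L)
    stop("g must be coprime with n for a full traversal")
  as.integer(((seq_len(n) - 1L) * as.integer(g)) %% n)
}

#' Subset samplers
#'
#' `new_sampler` creates a seeded sampler state; `sampler_next` draws the
#' next 0-based subset index. Strategies:
#' * `"herman_meyer"`: the fixed deterministic [herman_meyer_order()]
#'   every epoch;
#' * `"uniform_with"`: i.i.d. uniform with replacement;
#' * `"uniform_without"`: a fresh uniform permutation each epoch;
#' * `"fixed_without"`: one uniform permutation drawn at creation and
#'   reused every epoch (the "fixed random sequence" used by the ALG1/2
#'   presets);
#' * `"importance"`: with replacement under probabilities proportional to
#'   subset gradient norms (see [importance_probabilities()]; uniform
#'   until probabilities are supplied via [sampler_set_probabilities()]);
#' * `"cofactor"`: one [cofactor_traversal()] per epoch, cycling through
#'   the ranked generator list and reinitialising it once exhausted.
#'
#' The sampler keeps its own random number stream (derived from `seed`),
#' so identical seeds reproduce identical draw sequences regardless of
#' the surrounding RNG state.
#'
#' @param strategy one of the strategy names above.
#' @param n_subsets number of subsets.
#' @param seed integer seed for the sampler's private RNG stream.
#' @return `new_sampler` returns a sampler state (environment);
#'   `sampler_next` an integer in `0:(n_subsets-1)`.
#' @export
new_sampler <- function(strategy = c("uniform_without", "uniform_with",
                                     "fixed_without", "herman_meyer",
                                     "importance", "cofactor"),
                        n_subsets, seed = 1L) {
  strategy <- match.arg(strategy)
  n <- as.integer(n_subsets)
  if (n < 1L) stop("n_subsets must be >= 1")
  st <- new.env(parent = emptyenv())
  st$strategy <- strategy
  st$n <- n
  st$seed <- as.integer(seed)
  st$pos <- 0L          # cursor within the current epoch order
  st$epoch <- 0L
  st$epoch_order <- NULL
  st$probabilities <- NULL
  st$generator_queue <- if (strategy == "cofactor" && n >= 2L)
    cofactor_generators(n) else integer(0)
  st$queue_pos <- 0L
  st$rng <- init_rng(st$seed)
  if (strategy == "fixed_without")
    st$fixed_order <- with_sampler_rng(st, sample.int(n) - 1L)
  class(st) <- "subset_sampler"
  st
}

init_rng <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  rng <- get(".Random.seed", globalenv())
  restore_rng(old)
  rng
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

with_sampler_rng <- function(st, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", st$rng, envir = globalenv())
  on.exit({
    st$rng <- get(".Random.seed", globalenv())
    restore_rng(old)
  })
  expr
}

#' @export
print.subset_sampler <- function(x, ...) {
  cat("<subset_sampler> ", x$strategy, ", n=", x$n, ", seed=", x$seed,
      ", epoch ", x$epoch, "\n", sep = "")
  invisible(x)
}

new_epoch_order <- function(st) {
  switch(st$strategy,
    herman_meyer = herman_meyer_order(st$n),
    fixed_without = st$fixed_order,
    uniform_without = with_sampler_rng(st, sample.int(st$n) - 1L),
    cofactor = {
      if (st$n == 1L) return(0L)
      st$queue_pos <- st$queue_pos %% length(st$generator_queue) + 1L
      cofactor_traversal(st$n, st$generator_queue[st$queue_pos])
    },
    stop("not an epoch-ordered strategy"))
}

#' @rdname new_sampler
#' @param st a sampler state.
#' @export
sampler_next <- function(st) {
  if (st$strategy %in% c("uniform_with", "importance")) {
    p <- st$probabilities
    i <- with_sampler_rng(st,
      if (is.null(p)) sample.int(st$n, 1L)
      else sample.int(st$n, 1L, prob = p))
    st$pos <- st$pos + 1L
    if (st$pos >= st$n) {
      st$pos <- 0L
      st$epoch <- st$epoch + 1L
    }
    return(i - 1L)
  }
  if (st$pos == 0L) {
    st$epoch_order <- new_epoch_order(st)
    st$epoch <- st$epoch + 1L
  }
  st$pos <- st$pos + 1L
  i <- st$epoch_order[st$pos]
  if (st$pos >= st$n) st$pos <- 0L
  i
}

#' @rdname new_sampler
#' @param p probability vector over subsets (summing to 1).
#' @export
sampler_set_probabilities <- function(st, p) {
  if (length(p) != st$n || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a probability vector of length n_subsets")
  st$probabilities <- p
  invisible(st)
}

#' Importance-sampling probabilities from subset gradient norms
#'
#' `p_i = ||grad J_i|| / sum_j ||grad J_j||`. When every gradient is zero
#' the fallback is the uniform distribution.
#'
#' @param subset_gradients list of gradient arrays, one per subset.
#' @return numeric probability vector.
#' @export
importance_probabilities <- function(subset_gradients) {
  norms <- vapply(subset_gradients, function(g) sqrt(sum(g^2)), numeric(1))
  if (length(norms) == 0L) stop("need at least one subset gradient")
  s <- sum(norms)
  if (s == 0) return(rep(1 / length(norms), length(norms)))
  norms / s
}
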