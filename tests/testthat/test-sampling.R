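test_that("Herman-Meyer order reproduces the prime-decomposition construction", {
  expect_identical(herman_meyer_order(1), 0L)
  expect_identical(herman_meyer_order(2), c(0L, 1L))
  expect_identical(herman_meyer_order(4), c(0L, 2L, 1L, 3L))
  for (n in 2:64)
    expect_identical(sort(herman_meyer_order(n)), 0:(n - 1L))
  expect_error(herman_meyer_order(0), ">= 1")
})

test_that("cofactor generators and traversals reproduce the n = 15 worked example", {
  expect_identical(sort(cofactor_generators(15)),
                   c(2L, 4L, 7L, 8L, 11L, 13L, 14L))
  expect_identical(cofactor_generators(15),
                   c(4L, 11L, 2L, 8L, 7L, 13L, 14L))
  expect_identical(cofactor_traversal(15, 4),
                   c(0L, 4L, 8L, 12L, 1L, 5L, 9L, 13L, 2L, 6L, 10L,
                     14L, 3L, 7L, 11L))
  expect_identical(cofactor_generators(5), c(2L, 3L, 4L))
  expect_error(cofactor_traversal(15, 5), "coprime")
})

test_that("the cofactor sampler walks the ranked generator queue and restarts it", {
  st <- new_sampler("cofactor", 15, seed = 1)
  epoch1 <- replicate(15, sampler_next(st))
  expect_identical(epoch1, cofactor_traversal(15, 4))
  epoch2 <- replicate(15, sampler_next(st))
  expect_identical(epoch2, cofactor_traversal(15, 11))
  for (e in 3:7) replicate(15, sampler_next(st))
  epoch8 <- replicate(15, sampler_next(st))
  expect_identical(epoch8, cofactor_traversal(15, 4))  # queue reinitialised
})

test_that("every coprime generator yields a full cover of the subset indices", {
  for (n in 2:64) {
    gens <- cofactor_generators(n)
    for (g in gens)
      expect_identical(sort(cofactor_traversal(n, g)), 0:(n - 1L))
  }
})

test_that("uniform samplers cover each epoch or match binomial frequencies", {
  st <- new_sampler("uniform_without", 6, seed = 3)
  for (epoch in 1:4)
    expect_identical(sort(replicate(6, sampler_next(st))), 0:5)
  # with replacement: frequencies within 3 standard errors of 1/4
  stw <- new_sampler("uniform_with", 4, seed = 3)
  draws <- replicate(10000, sampler_next(stw))
  freq <- tabulate(draws + 1L, 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se))
  # fixed sequence: identical order in every epoch
  stf <- new_sampler("fixed_without", 8, seed = 5)
  e1 <- replicate(8, sampler_next(stf))
  e2 <- replicate(8, sampler_next(stf))
  expect_identical(e1, e2)
  expect_identical(sort(e1), 0:7)
})

test_that("identical seeds reproduce identical draw sequences", {
  for (strategy in c("uniform_with", "uniform_without", "fixed_without",
                     "importance", "cofactor", "herman_meyer")) {
    a <- new_sampler(strategy, 9, seed = 11)
    b <- new_sampler(strategy, 9, seed = 11)
    expect_identical(replicate(30, sampler_next(a)),
                     replicate(30, sampler_next(b)))
  }
  # and the sampler does not disturb the global RNG stream
  set.seed(99); r1 <- runif(3)
  set.seed(99)
  st <- new_sampler("uniform_without", 5, seed = 1)
  replicate(7, sampler_next(st))
  expect_identical(runif(3), r1)
})

test_that("importance probabilities are normalised gradient norms", {
  g1 <- matrix(1, 2, 2)
  expect_equal(importance_probabilities(list(g1, g1, g1)), rep(1 / 3, 3))
  expect_equal(importance_probabilities(list(3 * g1 / 2, g1 / 2)),
               c(0.75, 0.25))
  expect_equal(importance_probabilities(list(0 * g1, 0 * g1, 5 * g1)),
               c(0, 0, 1))
  expect_equal(importance_probabilities(list(0 * g1, 0 * g1)),
               c(0.5, 0.5))  # all-zero fallback
  st <- new_sampler("importance", 2, seed = 2)
  sampler_set_probabilities(st, c(0, 1))
  expect_identical(replicate(20, sampler_next(st)), rep(1L, 20))
  expect_error(sampler_set_probabilities(st, c(0.4, 0.4)), "probability")
})
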