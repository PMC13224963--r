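test_that("the six hexamodal peaks are the strain subsets' frequencies", {
  expect_equal(unname(peaks_from(c(1, 1, 1) / 3)),
               c(1, 1, 1, 2, 2, 2) / 3)
  expect_equal(unname(peaks_from(c(0.7, 0.2, 0.1))),
               c(0.7, 0.2, 0.1, 0.9, 0.8, 0.3))
  expect_equal(unname(peaks_from(c(1, 0, 0))), c(1, 0, 0, 1, 1, 0))
  expect_error(peaks_from(c(0.5, 0.2, 0.2)))
})

test_that("peak assignment is nearest-peak with deterministic ties", {
  dist <- c(0.7, 0.2, 0.1)
  a <- assign_peak(0.21, dist)
  expect_equal(a$subset, 2L)
  expect_equal(a$distance, 0.01)
  expect_equal(assign_peak(0.8, dist)$distance, 0)
  # exhaustive brute-force oracle over random frequencies
  set.seed(31)
  freqs <- runif(1000)
  got <- assign_peak(freqs, dist)
  p <- unname(peaks_from(dist))
  for (i in seq_along(freqs)) {
    d <- abs(freqs[i] - p)
    expect_equal(got$subset[i], which.min(d))
    expect_equal(got$distance[i], min(d))
  }
})

test_that("the score sums pair and complement distances to their peaks", {
  dist <- c(0.7, 0.2, 0.1)
  # exactly on peak {3} with complement exactly on {1,2}
  expect_equal(pair_score(0.1, dist), 0)
  # near peak {1}: 0.02 away, complement 0.32 lands 0.02 from {2,3}
  expect_equal(pair_score(0.68, dist), 0.04)
  d3 <- c(0.6, 0.25, 0.15)
  # 0.41 is 0.01 from {2,3}=0.40; complement 0.59 is 0.01 from {1}=0.60
  expect_equal(pair_score(0.41, d3), 0.02)
  # 0.32 is 0.07 from {2}=0.25; complement 0.68 is 0.07 from {1,3}=0.75
  expect_equal(pair_score(0.32, d3), 0.14)
  # ten-pair toy set against a hand-computed sum:
  # 0.41 and 0.59 are 0.11 from {2,3}=0.3 / {1}=0.7 respectively;
  # 0.25 ties between {2}=0.2 and {2,3}=0.3 at 0.05
  freqs <- c(0.10, 0.21, 0.68, 0.30, 0.79, 0.41, 0.90, 0.59, 0.25, 0.70)
  hand <- 0 + 0.02 + 0.04 + 0 + 0.02 + 0.22 + 0 + 0.22 + 0.10 + 0
  expect_equal(pair_score(freqs, dist), hand)
  # weights scale contributions linearly
  expect_equal(pair_score(c(0.1, 0.68), dist, weights = c(2, 3)),
               2 * 0 + 3 * 0.04)
})

test_that("complement symmetry keeps simplex scores penalty-free, and the
           unit penalty fires for incompatible assignments", {
  # On the simplex, peak k and its complement satisfy p_k + p_comp = 1,
  # so the complement frequency is always exactly as close to the
  # complementary peak as the pair is to its own: with ties resolved in
  # favour of compatibility, no pair can be penalized at 1.
  set.seed(36)
  for (rep in 1:20) {
    f <- as.numeric(straindecon:::cpp_big_jump(rep(1 / 3, 3)))
    freqs <- runif(200)
    s <- pair_score(freqs, f)
    p <- unname(peaks_from(f))
    d1 <- apply(abs(outer(freqs, p, "-")), 1, min)
    d2 <- apply(abs(outer(1 - freqs, p, "-")), 1, min)
    expect_equal(s, sum(d1 + d2), tolerance = 1e-9)
  }
  # the penalty branch itself, exercised through the scoring kernel on
  # a non-normalized peak configuration where the symmetry is broken:
  # peaks of (0.5, 0.3, 0.1): 0.29 is nearest {2}=0.3 (d 0.01), its
  # complement 0.71 is nearest {1,2}=0.8 (d 0.09) which is not the
  # complement of {2} -> contribution 1
  bad <- straindecon:::cpp_pair_score(0.29, 1, c(0.5, 0.3, 0.1))
  expect_equal(bad, 1)
})

test_that("R and C++ scorers agree on random instances", {
  set.seed(32)
  for (rep in 1:20) {
    freqs <- runif(50)
    w <- runif(50, 0.5, 2)
    f <- as.numeric(straindecon:::cpp_big_jump(rep(1 / 3, 3)))
    expect_equal(pair_score(freqs, f, w),
                 straindecon:::cpp_pair_score(freqs, w, f), tolerance = 1e-12)
  }
})

test_that("proposals stay on the simplex with the documented step scale", {
  set.seed(33)
  d0 <- c(0.5, 0.3, 0.2)
  props <- t(replicate(10000, straindecon:::cpp_propose(d0, 1)))
  expect_true(all(abs(rowSums(props) - 1) < 1e-9))
  expect_true(all(props >= 0 & props <= 1))
  # mean absolute change of the two shifted coordinates ~ E|signed
  # N(0.002, 0.002)| = 0.002 expected magnitude (approximately; the
  # complement coordinate absorbs both shifts)
  deltas <- abs(sweep(props, 2, d0))
  mean_shift <- mean(rowSums(deltas)) / 3
  expect_gt(mean_shift, 0.0005)
  expect_lt(mean_shift, 0.01)
})

test_that("big jumps scale the step or draw fresh from the simplex", {
  set.seed(34)
  d0 <- c(0.6, 0.3, 0.1)
  jumps <- t(replicate(4000, straindecon:::cpp_big_jump(d0)))
  expect_true(all(abs(rowSums(jumps) - 1) < 1e-9))
  moved <- rowSums(abs(sweep(jumps, 2, d0)))
  # the fresh-draw branch (1/4 of jumps) lands far from d0; uniform
  # simplex marginals have mean 1/3
  far <- jumps[moved > 0.25, , drop = FALSE]
  expect_gt(nrow(far), 400)
  # far moves are dominated by the fresh-draw branch; inflated-step
  # proposals leak in, so the uniform-simplex mean holds only loosely
  expect_equal(colMeans(far), rep(1 / 3, 3), tolerance = 0.3)
  # scaled branches keep moves of order 0.01-0.2
  expect_gt(mean(moved <= 0.25), 0.4)
})

test_that("seeded searches are bit-reproducible", {
  freqs <- c(rep(0.7, 30), rep(0.3, 30), rep(0.2, 20))
  a <- run_search(freqs, n_walkers = 50, seed = 99)
  b <- run_search(freqs, n_walkers = 50, seed = 99)
  expect_identical(a$freqs, b$freqs)
  expect_identical(a$score, b$score)
  expect_identical(a$trace, b$trace)
})

test_that("the score is invariant under strain relabeling", {
  set.seed(35)
  freqs <- runif(100)
  w <- runif(100, 1, 3)
  d <- c(0.55, 0.3, 0.15)
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  scores <- vapply(perms, function(p) pair_score(freqs, d[p], w), 0)
  expect_true(all(abs(scores - scores[1]) < 1e-9))
})

test_that("noise-free three-strain pair spectra are recovered", {
  truth <- c(0.7, 0.2, 0.1)
  p <- unname(peaks_from(truth))
  freqs <- rep(p, times = c(30, 30, 30, 20, 20, 20))
  fit <- run_search(freqs, seed = 41)
  expect_equal(fit$freqs, truth, tolerance = 0.02, ignore_attr = TRUE)
  expect_lt(fit$score, 0.05)
})

test_that("noise-free two-strain pair spectra collapse the third strain", {
  freqs <- rep(c(0.6, 0.4), times = c(60, 40))
  fit <- run_search(freqs, seed = 42)
  expect_lt(fit$freqs[3], 0.02)
  expect_equal(fit$freqs[1], 0.6, tolerance = 0.02)
})

test_that("greedy search never ends above the equal-frequency score", {
  set.seed(43)
  for (rep in 1:5) {
    freqs <- runif(40)
    fit <- run_search(freqs, n_walkers = 50, simplify = FALSE)
    expect_lte(fit$score, pair_score(freqs, rep(1 / 3, 3)) + 1e-9)
  }
})

test_that("the search dominates a dense simplex grid on toy instances", {
  set.seed(44)
  grid <- expand.grid(f1 = seq(0, 1, 0.01), f2 = seq(0, 1, 0.01))
  grid <- grid[grid$f1 + grid$f2 <= 1 + 1e-12, ]
  grid$f3 <- pmax(0, 1 - grid$f1 - grid$f2)
  for (rep in 1:3) {
    freqs <- runif(30)
    w <- rep(1, 30)
    fit <- run_search(freqs, w, n_walkers = 200, seed = 4400 + rep,
                      simplify = FALSE)
    gbest <- min(vapply(seq_len(nrow(grid)), function(i) {
      straindecon:::cpp_pair_score(freqs, w,
                                   as.numeric(grid[i, c("f1", "f2", "f3")]))
    }, 0))
    expect_lte(fit$score, gbest + 1e-6)
  }
})
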