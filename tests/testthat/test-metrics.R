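test_that("VP distance handles the textbook cases", {
  expect_equal(vp_distance(c(0.1, 0.2), c(0.1, 0.2)), 0)   # identity
  expect_equal(vp_distance(numeric(0), c(0.1, 0.5, 0.9)), 3)  # m insertions
  expect_equal(vp_distance(0.10, 0.30, q = 1), 0.2)  # shift beats delete+insert
  expect_equal(vp_distance(0.10, 0.90, q = 10), 2)   # far shift: delete+insert
  # q -> 0: spike count distance
  a <- sort(runif(7)); b <- sort(runif(3))
  expect_equal(vp_distance(a, b, q = 0), 4)
  expect_error(vp_distance(c(0.3, 0.1), c(0.2)), "sorted")
})

test_that("the DP equals the exhaustive edit-sequence minimum", {
  set.seed(20)
  for (rep in 1:150) {
    a <- random_train(sample(0:4, 1))
    b <- random_train(sample(0:4, 1))
    q <- sample(c(0, 0.5, 1, 4), 1)
    expect_equal(vp_distance(a, b, q), vp_brute(a, b, q), tolerance = 1e-12)
  }
})

test_that("the VP matrix satisfies the metric axioms", {
  set.seed(21)
  trains <- lapply(1:50, function(i) random_train(sample(2:12, 1)))
  D <- vp_distance_matrix(trains, q = 1)
  expect_true(all(diag(D) == 0))
  expect_identical(D, t(D))
  expect_true(all(D[upper.tri(D)] > 0))
  # triangle inequality on random triples
  for (rep in 1:1000) {
    ijk <- sample(50, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
  # consistency with pairwise calls
  for (rep in 1:5) {
    ij <- sample(50, 2)
    expect_equal(D[ij[1], ij[2]],
                 vp_distance(trains[[ij[1]]], trains[[ij[2]]], 1))
  }
  # all-identical trains -> zero matrix
  same <- replicate(4, c(0.1, 0.4, 0.9), simplify = FALSE)
  expect_true(all(vp_distance_matrix(same) == 0))
})

test_that("VP distance to a jittered copy grows with jitter", {
  set.seed(22)
  base <- random_train(30)
  sigmas <- c(0.001, 0.005, 0.02, 0.08)
  meand <- vapply(sigmas, function(s) {
    copies <- jittered_copies(base, s, 40, seed = 23, T = 1)
    mean(vapply(copies, function(cp) vp_distance(base, cp, 1), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meand) > 0))
})

test_that("firing rates and top-k selection", {
  expect_equal(firing_rate(seq(0.01, 0.99, length.out = 50), 1), 50)
  expect_equal(firing_rate(numeric(0), 2), 0)
  r <- homogeneous_poisson(20, 40, 1, seed = 3)
  expect_equal(firing_rates(r), lengths(r$times) / 1)
  # time-average of the windowed trace matches the mean rate
  tr <- mean_rate_trace(r, window = 0.02)
  expect_equal(mean(tr$rate), mean(firing_rates(r)), tolerance = 0.05)

  rates <- c(5, 9, 9, 1, 7)
  expect_identical(select_top_active(rates, 5), c(2L, 3L, 5L, 1L, 4L))
  expect_identical(select_top_active(rates, 1), 2L)  # tie: lower index wins
  expect_identical(select_top_active(rates, 2), c(2L, 3L))
})

test_that("rank_order reproduces the hand-ranked 3-neuron example", {
  # above-diagonal distances (d12, d13, d23) = (0.5, 0.2, 0.9)
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 0.5
  D[1, 3] <- D[3, 1] <- 0.2
  D[2, 3] <- D[3, 2] <- 0.9
  rates <- c(3, 2, 1)  # keep the original order under rate reindexing
  M <- rank_order(D, rates)$M
  # descending convention: 0.9 -> rank 0, 0.5 -> 1, 0.2 -> 2
  expect_equal(M[1, 2], 1 / 3)
  expect_equal(M[1, 3], 2 / 3)
  expect_equal(M[2, 3], 0 / 3)
  expect_equal(diag(M), rep(1, 3))
  Ma <- rank_order(D, rates, convention = "ascending")$M
  expect_equal(Ma[2, 3], 2 / 3)
  expect_equal(Ma[1, 3], 0)
  expect_equal(diag(Ma), rep(0, 3))
})

test_that("rank_order is a normalized order isomorphism", {
  set.seed(30)
  n <- 12
  K <- n * (n - 1) / 2
  D <- random_symmetric_matrix(n, max_val = 5)
  rates <- runif(n, 10, 90)
  rk <- rank_order(D, rates)
  M <- rk$M
  expect_identical(M, t(M))
  ut <- M[upper.tri(M)]
  expect_equal(sort(ut), (0:(K - 1)) / K)  # exact permutation of ranks
  expect_true(all(ut >= 0 & ut <= (K - 1) / K))
  # monotonicity: larger D <=> smaller M (default convention), checked on
  # the un-permuted pair order via the neuron ordering
  perm <- rk$neuron_order
  Dp <- D[perm, perm]
  iu <- which(upper.tri(D))
  expect_equal(order(Dp[iu]), order(-M[iu]))
  # invariance under strictly monotone transform of D
  rk2 <- rank_order(sqrt(D), rates)
  expect_identical(rk2$M, rk$M)
  # reindexing follows descending rates
  expect_identical(perm, order(-rates, seq_len(n)))
  expect_error(rank_order(matrix(c(0, NA, NA, 0), 2), c(1, 2)), "NaN/NA")
})

test_that("matrix CSV round-trips and validates symmetry", {
  set.seed(5)
  M <- random_symmetric_matrix(6)
  f <- tempfile(fileext = ".csv")
  write_matrix_csv(M, f)
  expect_equal(read_matrix_csv(f), M, tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- M; bad[1, 2] <- bad[1, 2] + 1
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_matrix_csv(f), "symmetric")
  unlink(f)
})
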