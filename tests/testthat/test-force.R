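test_that("P equals the closed-form regularized inverse after any update sequence", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    k <- sample(5:20, 1)
    alpha <- runif(1, 0.5, 5)
    rls <- rls_state(n, alpha)
    rs <- lapply(seq_len(k), function(i) rnorm(n))
    for (r in rs) rls <- rls_update(rls, r)
    expect_lt(max(abs(rls$P - rls_closed_form(alpha, rs))), 1e-8)
  }
})

test_that("P stays symmetric positive definite over long update sequences", {
  set.seed(7)
  rls <- rls_state(8, 1)
  for (i in 1:1000) rls <- rls_update(rls, rnorm(8))
  expect_equal(rls$P, t(rls$P))
  expect_gt(min(eigen(rls$P, symmetric = TRUE, only.values = TRUE)$values), 0)
  # r = 0 leaves P unchanged
  P0 <- rls$P
  rls <- rls_update(rls, numeric(8))
  expect_identical(rls$P, P0)
})

test_that("error and weight updates follow the RLS algebra", {
  W <- matrix(c(1, -2, 0.5, 3), 2, 2)
  r <- c(0.2, -0.4)
  z <- as.numeric(W %*% r)
  expect_equal(compute_error(W, r, z), c(0, 0))         # perfect readout
  expect_equal(compute_error(W, r, c(0, 0)), as.numeric(W %*% r))
  expect_error(compute_error(W, c(1, 2, 3), z), "shape mismatch")

  # hand-computed single-output, N = 2 case
  W1 <- matrix(c(0.5, -1), 1, 2)
  rls <- rls_state(2, alpha = 2)           # P = I/2
  e <- compute_error(W1, r, 0.3)           # 0.5*0.2 + (-1)*(-0.4) - 0.3 = 0.2
  expect_equal(e, 0.2)
  rls <- rls_update(rls, r)
  # P = I/2 - (r/2)(r/2)^T / (1 + r^T r / 2)
  P_hand <- diag(2) / 2 - tcrossprod(r / 2) / (1 + sum(r^2) / 2)
  expect_equal(rls$P, P_hand, tolerance = 1e-14)
  W2 <- weight_update(W1, rls, r, e)
  expect_equal(W2, W1 - 0.2 * t(P_hand %*% r), tolerance = 1e-14)
  # e = 0 leaves W unchanged
  expect_equal(weight_update(W1, rls, r, c(0)), W1)
  # post-update error on the same r is contracted
  e2 <- compute_error(W2, r, 0.3)
  expect_lt(abs(e2), abs(e))
})

test_that("a very large alpha freezes the readout", {
  set.seed(3)
  W <- matrix(rnorm(10), 2, 5)
  rls <- rls_state(5, alpha = 1e12)
  r <- rnorm(5)
  rls <- rls_update(rls, r)
  W2 <- weight_update(W, rls, r, compute_error(W, r, c(1, -1)))
  expect_lt(max(abs(W2 - W)), 1e-9)
})

test_that("RLS recovers a known linear readout of a frozen rate process", {
  # reservoir replaced by a frozen stochastic rate process; the target is a
  # fixed linear readout of it, which RLS must recover to high precision
  set.seed(11)
  n <- 40
  W_true <- matrix(rnorm(2 * n, sd = 0.5), 2, n)
  W <- matrix(0, 2, n)
  rls <- rls_state(n, alpha = 0.1)
  for (k in 1:6000) {
    r <- abs(rnorm(n, mean = 1))
    z <- as.numeric(W_true %*% r)
    e <- compute_error(W, r, z)
    rls <- rls_update(rls, r)
    W <- weight_update(W, rls, r, e)
  }
  set.seed(12)
  test_err <- replicate(200, {
    r <- abs(rnorm(n, mean = 1))
    sqrt(mean((as.numeric(W %*% r) - as.numeric(W_true %*% r))^2))
  })
  expect_lt(mean(test_err), 1e-3)
})

test_that("the in-loop trainer agrees with the R building blocks", {
  # same network, same schedule: C++ integrated training vs stepping the
  # simulator between updates and applying the R-level RLS operations
  conn <- init_connectivity(40, 2, p = 0.3, g = 0.4, q_fb = 10, seed = 21)
  pr <- neuron_params()
  tg <- target_spec("circle", dt = 1e-4)
  cfg <- train_config(total_time = 0.2, dt = 1e-4, dt_update = 2e-3,
                      alpha = 5, settle = 0.02, seed = 22)
  fit <- train_force(conn, pr, tg, cfg)

  n_steps <- 2000L
  teacher <- spiketopo:::target_teacher(tg, n_steps, 1e-4)
  st <- network_state(conn, pr, seed = 22)
  W <- conn$W
  rls <- rls_state(conn$N, alpha = 5)
  up <- 20L  # dt_update / dt
  settle <- 200L
  conn_run <- conn
  for (blk in seq_len(n_steps / up)) {
    conn_run$W <- W
    res <- spiketopo:::lif_drive(conn_run, pr, st, 1e-4, up)
    st <- spiketopo:::res_to_state(res)
    s_end <- blk * up
    if (s_end > settle) {
      e <- compute_error(W, st$r, teacher[s_end, ])
      rls <- rls_update(rls, st$r)
      W <- weight_update(W, rls, st$r, e)
    }
  }
  expect_equal(fit$conn$W, W, tolerance = 1e-8)
})

test_that("training preserves A and produces a bounded stable generator", {
  conn <- init_connectivity(200, 2, p = 0.2, g = 0.5, q_fb = 40, seed = 31)
  pr <- neuron_params()
  tg <- target_spec("circle")
  A_before <- conn$A
  fit <- train_force(conn, pr, tg, train_config(total_time = 1.5, seed = 32))
  expect_identical(fit$conn$A, A_before)          # A bit-identical
  expect_gt(sum(abs(fit$conn$W)), 0)              # W actually trained
  run <- run_network(fit$conn, pr, 3, state = fit$state)  # 3 periods
  z <- as.matrix(run$output[, -1])
  expect_true(all(is.finite(z)))
  expect_lt(max(abs(z)), 10 * tg$amplitude)       # bounded over 3 periods
})
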