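test_that("connectivity statistics match the generative description", {
  conn <- init_connectivity(2000, 2, p = 1, g = 1, q_fb = 0, seed = 7)
  vals <- as.numeric(conn$A)
  expect_lt(abs(stats::sd(vals) / (1 / sqrt(2000)) - 1), 0.02)
  expect_lt(abs(mean(vals)), 3 * (1 / sqrt(2000)) / sqrt(length(vals)) * 5)
  expect_true(all(conn$U == 0))  # q_fb = 0 degenerate uniform
  expect_true(all(conn$W == 0))

  conn2 <- init_connectivity(400, 2, p = 0.1, g = 0.5, q_fb = 3, seed = 1)
  frac <- Matrix::nnzero(conn2$A) / 400^2
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / 400^2))
  expect_true(all(abs(conn2$U) <= 3))
  expect_error(init_connectivity(5, 2, p = 0.1), "no connections")
})

test_that("connectivity and simulation are deterministic under a seed", {
  c1 <- init_connectivity(100, 2, seed = 3)
  c2 <- init_connectivity(100, 2, seed = 3)
  expect_identical(c1$A, c2$A)
  expect_identical(c1$U, c2$U)
  pr <- neuron_params()
  r1 <- run_network(c1, pr, 0.2, seed = 5)
  r2 <- run_network(c2, pr, 0.2, seed = 5)
  expect_identical(r1$raster$times, r2$raster$times)
  expect_identical(r1$output, r2$output)
})

test_that("effective coupling is A plus the low-rank feedback term", {
  conn <- init_connectivity(30, 2, p = 0.5, g = 1, q_fb = 2, seed = 2)
  expect_equal(effective_coupling(conn), as.matrix(conn$A))  # W = 0
  conn$W <- matrix(rnorm(2 * 30), 2, 30)
  Om <- effective_coupling(conn)
  expect_lte(qr(Om - as.matrix(conn$A))$rank, 2)
  # naive triple loop
  ref <- as.matrix(conn$A)
  for (i in 1:30) for (j in 1:30) for (k in 1:2)
    ref[i, j] <- ref[i, j] + conn$U[i, k] * conn$W[k, j]
  expect_equal(Om, ref, tolerance = 1e-12)
})

test_that("readout equals the naive weighted sum", {
  conn <- init_connectivity(20, 3, p = 0.5, seed = 1)
  st <- network_state(conn, neuron_params(), seed = 1)
  st$r <- runif(20)
  expect_equal(readout(conn, st), rep(0, 3))  # W = 0
  conn$W <- matrix(rnorm(60), 3, 20)
  expect_equal(readout(conn, st), as.numeric(conn$W %*% st$r))
  conn$W[] <- 0
  conn$W[1, 1] <- 2.5
  expect_equal(readout(conn, st), c(2.5 * st$r[1], 0, 0))
})

test_that("an uncoupled neuron at rest with no bias never spikes", {
  conn <- init_connectivity(1, 1, p = 1, g = 0, q_fb = 0, seed = 1)
  pr <- neuron_params(I_bias = 0)
  st <- network_state(conn, pr, kick = 0)
  st$v[] <- pr$v_rest
  run <- run_network(conn, pr, 0.5, state = st, record_every = 0L)
  expect_identical(sum(lengths(run$raster$times)), 0L)
})

test_that("constant-drive LIF inter-spike interval matches the closed form", {
  conn <- init_connectivity(1, 1, p = 1, g = 0, q_fb = 0, seed = 1)
  dt <- 5e-5
  for (I in c(30, 50, 80)) {
    pr <- neuron_params(I_bias = I)
    st <- network_state(conn, pr, kick = 0)
    st$v[] <- pr$v_rest
    run <- run_network(conn, pr, 0.5, dt = dt, state = st, record_every = 0L)
    isi <- diff(run$raster$times[[1]])
    v_inf <- pr$v_rest + I
    theory <- pr$tau_ref +
      pr$tau_m * log((v_inf - pr$v_reset) / (v_inf - pr$v_th))
    expect_lt(abs(mean(isi) - theory), 2 * dt)
  }
})

test_that("the synaptic filter has unit area and the analytic peak", {
  # one spike into the double-exponential filter:
  # r(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / (tau_d - tau_r)
  pr <- neuron_params()
  conn <- init_connectivity(1, 1, p = 1, g = 0, q_fb = 0, seed = 1)
  dt <- 5e-5
  st <- network_state(conn, pr, kick = 0)
  st$v[] <- pr$v_th + 1  # spike in the first step
  n_steps <- 4000L  # 0.2 s >> tau_decay
  res <- spiketopo:::lif_drive(conn, pr, st, dt, 1L)
  expect_identical(res$spike_id, 0L)
  r_trace <- numeric(n_steps)
  st2 <- spiketopo:::res_to_state(res)
  tt <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    res <- spiketopo:::lif_drive(conn, pr, st2, dt, 1L)
    st2 <- spiketopo:::res_to_state(res)
    st2$v[] <- pr$v_rest  # keep it from spiking again
    r_trace[s] <- st2$r
    tt[s] <- s * dt
  }
  analytic <- (exp(-tt / pr$tau_decay) - exp(-tt / pr$tau_rise)) /
    (pr$tau_decay - pr$tau_rise)
  expect_lt(max(abs(r_trace - analytic)), 1e-3 * max(analytic))
  expect_lt(abs(sum(r_trace) * dt - 1), 1e-3)  # unit area
  t_peak <- log(pr$tau_decay / pr$tau_rise) /
    (1 / pr$tau_rise - 1 / pr$tau_decay)
  expect_lt(abs(tt[which.max(r_trace)] - t_peak), 2 * dt)
})

test_that("rasters respect refractoriness and the threshold-reset invariant", {
  conn <- init_connectivity(50, 2, p = 0.2, g = 0.6, q_fb = 5, seed = 4)
  pr <- neuron_params()
  run <- run_network(conn, pr, 0.5, seed = 9)
  isis <- unlist(lapply(run$raster$times, diff))
  expect_gte(length(isis), 10)
  expect_true(all(isis >= pr$tau_ref))
  expect_true(all(run$state$v <= pr$v_th + 1e-9))
})

test_that("spike times converge as dt shrinks (10-neuron self-convergence)", {
  conn <- init_connectivity(10, 2, p = 0.5, g = 0.4, q_fb = 5, seed = 6)
  pr <- neuron_params()
  st0 <- network_state(conn, pr, seed = 2)
  run1 <- run_network(conn, pr, 0.1, dt = 5e-5, state = st0)
  run2 <- run_network(conn, pr, 0.1, dt = 2.5e-5, state = st0)
  # compare first spike time per neuron where both produced one
  f1 <- vapply(run1$raster$times, function(x) if (length(x)) x[1] else NA_real_,
               numeric(1))
  f2 <- vapply(run2$raster$times, function(x) if (length(x)) x[1] else NA_real_,
               numeric(1))
  both <- !is.na(f1) & !is.na(f2)
  expect_gte(sum(both), 5)
  expect_lt(max(abs(f1[both] - f2[both])), 20 * 5e-5)
})

test_that("mean_rate_trace counts windows correctly", {
  # 10 neurons, 50 uniform spikes each in 1 s -> flat 50 Hz
  times <- replicate(10, seq(0.01, 0.99, length.out = 50), simplify = FALSE)
  r <- spike_raster(times, 1)
  tr <- mean_rate_trace(r, window = 0.02)
  expect_equal(tr$rate, rep(50, nrow(tr)), tolerance = 1e-9)
  # empty raster -> all zero
  r0 <- spike_raster(replicate(5, numeric(0), simplify = FALSE), 1)
  expect_true(all(mean_rate_trace(r0, 0.02)$rate == 0))
})

test_that("rate trace tracks an inhomogeneous Poisson profile", {
  # lambda(t) = 40 + 30 sin(2 pi t): compare windowed trace to the profile
  spec <- synth_spec(n_neurons = 200, petals = 1, rate_band = c(10, 70),
                     phase_concentration = 1, phase_jitter = 0, seed = 31)
  r <- petal_modulated_raster(spec)
  tr <- mean_rate_trace(r, window = 0.02)
  centers <- attr(r, "centers")
  lam <- spiketopo:::petal_lambda(spec, centers, attr(r, "depth"), tr$time)
  expect_lt(max(abs(tr$rate - colMeans(lam))), 12)  # ~3 s.e. at this n
})

test_that("raster CSV round-trips and reports malformed rows", {
  r <- homogeneous_poisson(5, 30, 1, seed = 8)
  f <- tempfile(fileext = ".csv")
  write_raster_csv(r, f)
  back <- read_raster_csv(f, n_neurons = 5, duration = 1)
  expect_equal(back$times, r$times, tolerance = 1e-12)
  writeLines(c("neuron_id,spike_time_s", "0,0.1", "oops,not_a_number"), f)
  expect_error(read_raster_csv(f), "line 3")
  unlink(f)
})
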