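# Trained-network runs are expensive, so they are computed once per session
# and shared by the tests that examine them (rate bands, trajectory RMSE,
# petal phase structure).

trained_runs <- new.env(parent = emptyenv())

get_trained_run <- function(shape, N = 1000) {
  key <- paste0(shape, "_", N)
  if (!is.null(trained_runs[[key]])) return(trained_runs[[key]])
  pr <- neuron_params()
  tg <- target_spec(shape)
  conn <- init_connectivity(N, 2, p = 0.1, g = 1, q_fb = 40, seed = 1)
  cal <- calibrate_gain(conn, pr, tg,
                        rate_target = if (shape == "circle") 78 else 50,
                        seed = 3)
  conn <- set_gain(conn, cal$g)
  fit <- train_force(conn, pr, tg, train_config(seed = 2))
  ev <- run_trajectory_eval(fit$conn, tg, pr, state = fit$state)
  rt <- mean_rate_trace(ev$raster, window = 0.02)
  out <- list(fit = fit, ev = ev, rate_trace = rt, calib = cal)
  trained_runs[[key]] <- out
  out
}
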