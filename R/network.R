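# Recurrent LIF reservoir: parameters, random connectivity, and simulation.
#
# Model (per neuron i):
#   tau_m dv_i/dt = v_rest - v_i + I_bias + sum_j omega_ij r_j
# with omega = A + U W (fixed sparse recurrent A, fixed random feedback U,
# trained readout W), threshold v_th, reset v_reset, absolute refractory
# period tau_ref, and the double-exponential synaptic filter
#   dr_i/dt = -r_i/tau_decay + h_i
#   dh_i/dt = -h_i/tau_rise + (1/(tau_rise*tau_decay)) sum_k delta(t - t_k^i)
# so that each spike contributes unit area to r_i.  The readout is
#   zhat = W r  (M outputs), fed back as current U zhat.
# All times are in seconds, voltages in mV.

#' LIF neuron and synapse parameters
#'
#' Defaults follow the standard parameterization for FORCE-trained LIF
#' reservoirs: `tau_m` 10 ms, `v_rest` = `v_reset` = -65 mV, `v_th` -40 mV,
#' absolute refractory period 2 ms, synaptic rise 2 ms and decay 20 ms.
#' `I_bias` defaults to `v_th - v_rest` (25 mV), which places the bias-free
#' equilibrium exactly at threshold so the network is excitable without
#' external input; recurrent and feedback currents then drive fluctuation-
#' driven spiking.
#'
#' All times are in seconds, voltages in mV.
#'
#' @param tau_m membrane time constant (s).
#' @param v_rest resting potential (mV).
#' @param v_th spike threshold (mV).
#' @param v_reset post-spike reset potential (mV).
#' @param tau_ref absolute refractory period (s); the voltage is clamped at
#'   `v_reset` and input is ignored.
#' @param tau_rise,tau_decay synaptic rise / decay time constants (s); must
#'   differ.
#' @param I_bias constant bias drive (mV).
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 0.01, v_rest = -65, v_th = -40,
                          v_reset = -65, tau_ref = 0.002,
                          tau_rise = 0.002, tau_decay = 0.02,
                          I_bias = 25) {
  stopifnot(tau_m > 0, tau_ref > 0, tau_rise > 0, tau_decay > 0,
            tau_rise != tau_decay, v_reset <= v_th, v_rest < v_th)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_th = v_th,
                 v_reset = v_reset, tau_ref = tau_ref, tau_rise = tau_rise,
                 tau_decay = tau_decay, I_bias = I_bias),
            class = "neuron_params")
}

#' Initialize reservoir connectivity
#'
#' Recurrent weights `A` are sparse: each entry is nonzero with probability
#' `p` and nonzero entries are Gaussian with zero mean and standard
#' deviation `g / sqrt(p N)`.  Feedback weights `U` (N x M) are uniform on
#' `[-q_fb, q_fb]`.  The readout `W` (M x N) starts at zero.  The diagonal
#' of `A` is drawn like any other entry.
#'
#' @param N number of neurons.
#' @param M number of readout units (2 for planar targets).
#' @param p connection probability; `p * N >= 1` required.
#' @param g global recurrent coupling gain (mV per unit filtered rate); see
#'   [calibrate_gain()] for tuning it to a firing-rate band.
#' @param q_fb feedback strength: entries of `U` are uniform on
#'   `[-q_fb, q_fb]` (mV per output unit).
#' @param seed RNG seed (connectivity is reproducible under a fixed seed).
#' @return an object of class `connectivity` with elements `A`
#'   (`Matrix::dgCMatrix`), `U`, `W`, and the scalars `N`, `M`, `p`, `g`,
#'   `q_fb`.
#' @export
init_connectivity <- function(N, M = 2, p = 0.1, g = 0.2, q_fb = 40,
                              seed = NULL) {
  stopifnot(N > 0, M >= 1, p > 0, p <= 1, g >= 0, q_fb >= 0)
  if (p * N < 1) stop("p * N < 1: no connections possible")
  with_seed(seed, {
    nz <- which(runif(N * N) < p)
    vals <- rnorm(length(nz), mean = 0, sd = 1 / sqrt(p * N))
    A <- Matrix::sparseMatrix(i = ((nz - 1) %% N) + 1,
                              j = ((nz - 1) %/% N) + 1,
                              x = g * vals, dims = c(N, N))
    U <- matrix(runif(N * M, -q_fb, q_fb), N, M)
    structure(list(A = A, U = U, W = matrix(0, M, N),
                   N = as.integer(N), M = as.integer(M),
                   p = p, g = g, q_fb = q_fb),
              class = "connectivity")
  })
}

#' Rescale the recurrent gain of an existing connectivity
#'
#' Rescales `A` in place to gain `g` (the sparsity pattern and the
#' underlying Gaussian draw are preserved), so gain sweeps explore the same
#' network at different coupling strengths.
#'
#' @param conn a [init_connectivity()] object.
#' @param g new gain.
#' @export
set_gain <- function(conn, g) {
  stopifnot(inherits(conn, "connectivity"), g >= 0, conn$g > 0)
  conn$A <- conn$A * (g / conn$g)
  conn$g <- g
  conn
}

#' Effective coupling matrix
#'
#' The autonomous network evolves under `Omega = A + U %*% W`: the fixed
#' recurrent matrix plus the (at most rank-M) perturbation contributed by
#' the feedback loop through the trained readout.
#'
#' @param conn a [init_connectivity()] object.
#' @return dense N x N matrix.
#' @export
effective_coupling <- function(conn) {
  stopifnot(inherits(conn, "connectivity"))
  if (ncol(conn$U) != nrow(conn$W) || ncol(conn$W) != nrow(conn$A))
    stop("shape mismatch between A, U and W")
  as.matrix(conn$A) + conn$U %*% conn$W
}

#' Linear readout of the filtered rates
#'
#' @param conn a [init_connectivity()] object (uses its `W`).
#' @param state a [network_state()] (uses its `r`).
#' @return numeric vector of M outputs `zhat = W r`.
#' @export
readout <- function(conn, state) {
  as.numeric(conn$W %*% state$r)
}

#' Fresh network state
#'
#' Voltages start uniform on `[v_rest, v_th + kick * (v_th - v_rest)]`
#' (seeded); synaptic variables and refractory clocks start at zero.  With
#' the default `kick = 1`, half of the neurons start above threshold and
#' fire in the first step: this initial burst kicks the reservoir into the
#' self-sustained activity from which FORCE training (and autonomous
#' generation) proceeds, since with the bias at threshold a network started
#' strictly below threshold would never fire.
#'
#' @param conn connectivity (for N).
#' @param params [neuron_params()].
#' @param seed RNG seed for the initial voltages.
#' @param kick width of the above-threshold part of the initial voltage
#'   distribution, in units of `v_th - v_rest`; 0 starts every neuron below
#'   threshold.
#' @export
network_state <- function(conn, params, seed = NULL, kick = 1) {
  N <- conn$N
  stopifnot(kick >= 0)
  with_seed(seed, {
    v_hi <- params$v_th + kick * (params$v_th - params$v_rest)
    structure(list(v = runif(N, params$v_rest, v_hi),
                   r = numeric(N), h = numeric(N),
                   refractory_remaining = numeric(N), t = 0),
              class = "network_state")
  })
}

# Shared low-level driver around the compiled simulator.
lif_drive <- function(conn, params, state, dt, n_steps, teacher = NULL,
                      teacher_feedback = FALSE, train = FALSE,
                      settle_steps = 0L, update_every = 1L, alpha = 1,
                      record_every = 0L) {
  if (is.null(teacher)) teacher <- matrix(0, 0, conn$M)
  cpp_lif_run(conn$A, conn$U, conn$W,
              params$tau_m, params$v_rest, params$v_th, params$v_reset,
              params$tau_ref, params$tau_rise, params$tau_decay,
              params$I_bias,
              dt, as.integer(n_steps),
              state$v, state$r, state$h, state$refractory_remaining,
              state$t,
              teacher, teacher_feedback, train,
              as.integer(settle_steps), as.integer(update_every), alpha,
              as.integer(record_every))
}

res_to_state <- function(res) {
  structure(list(v = res$v, r = res$r, h = res$h,
                 refractory_remaining = res$refr, t = res$t_end),
            class = "network_state")
}

#' Advance the network by one Euler step
#'
#' Forward-Euler voltage update with exact exponential integration of the
#' synaptic pair within the step; neurons crossing threshold spike, reset
#' and freeze for the refractory period, and their `h` increments by
#' `1/(tau_rise * tau_decay)` (unit-area filter).
#'
#' @param state a [network_state()].
#' @param conn connectivity.
#' @param params [neuron_params()].
#' @param dt step in seconds (must resolve `tau_rise` and `tau_m`).
#' @param feedback `"own"` feeds back the network's readout `W r`;
#'   `"none"` disables the feedback current.
#' @return list with elements `state` and `spiked` (integer ids, 1-based).
#' @export
lif_step <- function(state, conn, params, dt, feedback = c("own", "none")) {
  feedback <- match.arg(feedback)
  stopifnot(dt > 0)
  conn2 <- conn
  if (feedback == "none") conn2$U <- matrix(0, conn$N, conn$M)
  res <- lif_drive(conn2, params, state, dt, 1L)
  list(state = res_to_state(res), spiked = res$spike_id + 1L)
}

#' Run the network for a stretch of time
#'
#' Autonomous simulation: the feedback current is `U %*% zhat` with the
#' network's own readout `zhat = W r` (or the teacher signal when
#' `teacher_feedback = TRUE`, as used for gain calibration).
#'
#' @param conn connectivity.
#' @param params [neuron_params()].
#' @param duration simulated time (s).
#' @param dt integration step (s).
#' @param seed seed for the initial state (ignored when `state` is given).
#' @param state optional [network_state()] to continue from.
#' @param teacher optional matrix (`n_steps` x M) of teacher values, required
#'   when `teacher_feedback = TRUE`.
#' @param teacher_feedback feed the teacher signal back instead of `zhat`.
#' @param record_every record the readout every this many steps (0 = off).
#' @return list with `raster` ([spike_raster()]), `output` (data.frame
#'   `time`, `z1`, ..., `zM`), and `state` (final state; its `t` continues
#'   from the initial state).  Spike times in `raster` are relative to the
#'   start of this run.
#' @export
run_network <- function(conn, params, duration, dt = 5e-5, seed = NULL,
                        state = NULL, teacher = NULL,
                        teacher_feedback = FALSE, record_every = 20L) {
  stopifnot(inherits(conn, "connectivity"), duration > 0, dt > 0)
  if (is.null(state)) state <- network_state(conn, params, seed = seed)
  n_steps <- as.integer(round(duration / dt))
  t0 <- state$t
  state$t <- 0  # raster times relative to run start
  res <- lif_drive(conn, params, state, dt, n_steps, teacher = teacher,
                   teacher_feedback = teacher_feedback,
                   record_every = record_every)
  raster <- raster_from_events(res$spike_id + 1L, res$spike_t, conn$N,
                               n_steps * dt)
  out <- data.frame(time = res$t_trace)
  z <- res$z_trace
  for (k in seq_len(ncol(z))) out[[paste0("z", k)]] <- z[, k]
  st <- res_to_state(res)
  st$t <- t0 + n_steps * dt
  list(raster = raster, output = out, state = st)
}
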