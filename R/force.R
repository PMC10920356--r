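# FORCE training of the readout matrix W by recursive least squares (RLS).
#
# Every update interval (after an initial settle period):
#   e(t)  = W r(t) - z(t)                         (error, M-vector)
#   P(t)  = P - (P r)(P r)^T / (1 + r^T P r)      (inverse-correlation est.)
#   W(t)  = W - e (P(t) r)^T
# with P initialized to I/alpha.  P converges to the regularized inverse
# (alpha I + sum r r^T)^{-1}, and the post-update error on the same r is
# contracted by 1/(1 + r^T P r) >= ... < 1, which is what makes FORCE stable
# from the first update on.

#' RLS state
#'
#' @param n dimension (number of neurons feeding the readout).
#' @param alpha learning-rate parameter; `P` is initialized to `I/alpha`
#'   (small `alpha` = aggressive early updates, large `alpha` = strong
#'   regularization).
#' @return object of class `rls_state` with the running `P` matrix.
#' @export
rls_state <- function(n, alpha = 20) {
  stopifnot(n >= 1, alpha > 0)
  structure(list(P = diag(n) / alpha, alpha = alpha, n = as.integer(n)),
            class = "rls_state")
}

#' Readout error against the teacher
#'
#' @param W readout matrix (M x N).
#' @param r filtered-rate vector (length N).
#' @param z_target teacher value (length M).
#' @return error vector `e = W r - z_target`.
#' @export
compute_error <- function(W, r, z_target) {
  if (ncol(W) != length(r) || nrow(W) != length(z_target))
    stop("shape mismatch: W is ", nrow(W), "x", ncol(W), ", r has length ",
         length(r), ", z_target has length ", length(z_target))
  as.numeric(W %*% r - z_target)
}

#' One RLS update of the inverse-correlation estimate
#'
#' @param rls an [rls_state()].
#' @param r rate vector.
#' @return the updated `rls_state`; `P` is re-symmetrized after the rank-one
#'   update to keep it positive definite over long runs.
#' @export
rls_update <- function(rls, r) {
  stopifnot(inherits(rls, "rls_state"), length(r) == rls$n)
  Pr <- rls$P %*% r
  denom <- 1 + sum(r * Pr)
  P <- rls$P - tcrossprod(Pr) / denom
  if (any(!is.finite(P))) stop("non-finite P in RLS update")
  rls$P <- (P + t(P)) / 2
  rls
}

#' One weight update
#'
#' @param W readout matrix (M x N).
#' @param rls [rls_state()] *after* the corresponding [rls_update()].
#' @param r rate vector.
#' @param e error computed with the pre-update `W` at this instant.
#' @return updated `W = W - e (P r)^T`.
#' @export
weight_update <- function(W, rls, r, e) {
  if (ncol(W) != length(r) || nrow(W) != length(e))
    stop("shape mismatch in weight_update")
  W - tcrossprod(e, as.numeric(rls$P %*% r))
}

#' Training configuration
#'
#' @param total_time total training time (s).
#' @param dt simulator step (s).
#' @param dt_update RLS update interval (s); must be a multiple of `dt` and
#'   larger than it.
#' @param alpha RLS learning-rate parameter (see [rls_state()]).
#' @param settle initial settle time without updates (s).
#' @param seed seed for the initial network state.
#' @param tol_dW stop early once the Frobenius norm of the change of `W`
#'   over one target period drops below this value (0 disables early
#'   stopping).
#' @param teacher_feedback during training, feed back the teacher `z(t)`
#'   instead of the network's own readout `zhat` (classic FORCE uses the
#'   network's own output; this is the default).
#' @export
train_config <- function(total_time = 4, dt = 5e-5, dt_update = 2e-3,
                         alpha = 20, settle = 0.1, seed = NULL,
                         tol_dW = 0, teacher_feedback = FALSE) {
  stopifnot(total_time > 0, dt > 0, dt_update > dt, alpha > 0, settle >= 0,
            tol_dW >= 0)
  if (abs(dt_update / dt - round(dt_update / dt)) > 1e-9)
    stop("dt_update must be an integer multiple of dt")
  structure(list(total_time = total_time, dt = dt, dt_update = dt_update,
                 alpha = alpha, settle = settle, seed = seed,
                 tol_dW = tol_dW, teacher_feedback = teacher_feedback),
            class = "train_config")
}

#' FORCE-train the readout on a target curve
#'
#' Simulates the network while updating `W` by RLS every `dt_update`,
#' tiling the target periodically over the training time.  Training runs in
#' chunks of one target period; after each chunk the per-period change of
#' `W` is compared against `tol_dW` for early stopping.
#'
#' @param conn connectivity (its `W` is the starting readout, normally all
#'   zeros).
#' @param params [neuron_params()].
#' @param target a [target_spec()].
#' @param cfg a [train_config()].
#' @param state optional starting [network_state()].
#' @return list with `conn` (trained `W`; `A` and `U` untouched), `errors`
#'   (data.frame `t`, `rmse` of the pre-update error per interval), `state`
#'   (network state at the end of training, from which autonomous
#'   generation should continue), and `stopped_early`.
#' @export
train_force <- function(conn, params, target, cfg = train_config(),
                        state = NULL) {
  stopifnot(inherits(conn, "connectivity"), inherits(target, "target_spec"),
            inherits(cfg, "train_config"))
  dt <- cfg$dt
  period_steps <- as.integer(round(target$duration / dt))
  total_steps <- as.integer(round(cfg$total_time / dt))
  teacher_period <- target_teacher(target, period_steps, dt)
  if (is.null(state))
    state <- network_state(conn, params, seed = cfg$seed)
  settle_steps <- as.integer(round(cfg$settle / dt))
  update_every <- as.integer(round(cfg$dt_update / dt))

  err_t <- numeric(0)
  err_rmse <- numeric(0)
  stopped <- FALSE
  t_off <- 0
  steps_left <- total_steps
  ch <- 0L
  while (steps_left > 0L) {
    ch <- ch + 1L
    chunk_steps <- min(period_steps, steps_left)
    steps_left <- steps_left - chunk_steps
    W_prev <- conn$W
    res <- lif_drive(conn, params, state, dt, chunk_steps,
                     teacher = teacher_period,
                     teacher_feedback = cfg$teacher_feedback,
                     train = TRUE, settle_steps = settle_steps,
                     update_every = update_every, alpha = cfg$alpha)
    conn$W <- res$W
    state <- res_to_state(res)
    state$t <- 0
    settle_steps <- max(0L, settle_steps - chunk_steps)
    err_t <- c(err_t, t_off + res$err_t)
    err_rmse <- c(err_rmse, res$err_rmse)
    t_off <- t_off + chunk_steps * dt
    n <- length(err_rmse)
    if (n > 20) {
      head_err <- mean(err_rmse[seq_len(10)])
      tail_err <- mean(err_rmse[(n - 9):n])
      if (!is.finite(tail_err) ||
          (tail_err > 100 * max(head_err, 1) && tail_err > 10))
        stop("FORCE training diverged (RMSE growing without bound); ",
             "reduce the coupling gain g or increase alpha")
    }
    dW <- sqrt(sum((conn$W - W_prev)^2))
    if (cfg$tol_dW > 0 && ch > 1 && dW < cfg$tol_dW) {
      stopped <- TRUE
      break
    }
  }
  list(conn = conn,
       errors = data.frame(t = err_t, rmse = err_rmse),
       state = state, stopped_early = stopped)
}

#' Calibrate the recurrent gain to a target firing rate
#'
#' Short teacher-forced simulations (the target signal is fed back through
#' `U` while `W = 0`) are run at different gains `g`, and the gain whose
#' mean population rate is closest to `rate_target` is found by bisection.
#' The population rate of the trained autonomous network closely tracks the
#' teacher-forced rate, so this puts the trained network into the desired
#' firing-rate band without running full training.
#'
#' @param conn connectivity (pattern and `U` are reused across gains via
#'   [set_gain()]).
#' @param params [neuron_params()].
#' @param target [target_spec()].
#' @param rate_target desired mean population rate (Hz).
#' @param g_range interval of gains to search.
#' @param dur simulated time per evaluation (s); the first `discard` seconds
#'   are excluded from the rate estimate.
#' @param discard initial transient to discard (s).
#' @param tol stop when the achieved rate is within `tol` Hz of the target.
#' @param max_iter bisection iteration cap.
#' @param seed seed for the initial state (shared across evaluations).
#' @return list with `g`, `rate` (achieved mean rate), and `trace` of the
#'   evaluated `(g, rate)` pairs.
#' @export
calibrate_gain <- function(conn, params, target, rate_target = 60,
                           g_range = c(0.02, 1), dur = 0.4, discard = 0.1,
                           tol = 2, max_iter = 12, seed = 1) {
  stopifnot(inherits(conn, "connectivity"), rate_target > 0,
            length(g_range) == 2, g_range[1] > 0, g_range[2] > g_range[1])
  dt <- target$dt
  n_steps <- as.integer(round(dur / dt))
  teacher <- target_teacher(target, n_steps, dt)

  eval_rate <- function(g) {
    cg <- set_gain(conn, g)
    run <- run_network(cg, params, dur, dt = dt, seed = seed,
                       teacher = teacher, teacher_feedback = TRUE,
                       record_every = 0L)
    tt <- unlist(run$raster$times, use.names = FALSE)
    sum(tt >= discard) / (conn$N * (dur - discard))
  }

  lo <- g_range[1]; hi <- g_range[2]
  r_lo <- eval_rate(lo); r_hi <- eval_rate(hi)
  trace <- data.frame(g = c(lo, hi), rate = c(r_lo, r_hi))
  # expand upward if even the top of the range is too quiet
  while (r_hi < rate_target && hi < 8 * g_range[2]) {
    hi <- 2 * hi
    r_hi <- eval_rate(hi)
    trace <- rbind(trace, data.frame(g = hi, rate = r_hi))
  }
  best <- trace[which.min(abs(trace$rate - rate_target)), ]
  for (it in seq_len(max_iter)) {
    if (abs(best$rate - rate_target) <= tol) break
    mid <- sqrt(lo * hi)  # geometric bisection on the gain
    r_mid <- eval_rate(mid)
    trace <- rbind(trace, data.frame(g = mid, rate = r_mid))
    if (abs(r_mid - rate_target) < abs(best$rate - rate_target))
      best <- data.frame(g = mid, rate = r_mid)
    if (r_mid < rate_target) { lo <- mid; r_lo <- r_mid }
    else { hi <- mid; r_hi <- r_mid }
  }
  list(g = best$g, rate = best$rate, trace = trace)
}

#' Serialize a connectivity (trained or not) to a single archive
#'
#' The archive is an RDS file holding a plain list with the four arrays
#' (`A` as a base dense matrix, `U`, `W`) plus the neuron parameters and
#' scalars (`N`, `M`, `p`, `g`, `q_fb`).
#'
#' @param conn connectivity.
#' @param params [neuron_params()] stored alongside.
#' @param path file path.
#' @export
write_connectivity <- function(conn, params, path) {
  saveRDS(list(A = as.matrix(conn$A), U = conn$U, W = conn$W,
               N = conn$N, M = conn$M, p = conn$p, g = conn$g,
               q_fb = conn$q_fb, params = unclass(params)),
          path)
  invisible(path)
}

#' @rdname write_connectivity
#' @return `read_connectivity` returns a list with elements `conn` and
#'   `params`.
#' @export
read_connectivity <- function(path) {
  x <- readRDS(path)
  conn <- structure(list(A = Matrix::Matrix(x$A, sparse = TRUE),
                         U = x$U, W = x$W, N = x$N, M = x$M, p = x$p,
                         g = x$g, q_fb = x$q_fb),
                    class = "connectivity")
  list(conn = conn, params = do.call(neuron_params, x$params))
}
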