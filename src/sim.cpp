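// Leaky integrate-and-fire reservoir with double-exponential synapses,
// linear readout fed back through fixed random weights, and optional
// in-loop recursive-least-squares (FORCE) training of the readout.
//
// The integration scheme is forward Euler for the voltage and the exact
// exponential update for the (r, h) synaptic pair within each step.  All
// randomness (connectivity, initial voltages) is injected from R; this
// translation unit is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Simulate (and optionally train) for n_steps of size dt, starting from the
// supplied state.  teacher is an n_steps x M matrix of target values (may be
// 0 x 0 when neither training nor teacher feedback is requested).
//
// feedback: the synaptic drive is A*r + U*fb where fb is the network's own
// readout W*r (classic FORCE) or the teacher row (teacher forcing).
//
// Training: every update_every steps after settle_steps, with z the teacher
// row at the update instant,
//   e  = W r - z
//   P <- P - (P r)(P r)^T / (1 + r^T P r)   (then re-symmetrized)
//   W <- W - e (P r)^T
// P is initialized to I/alpha.
// [[Rcpp::export]]
List cpp_lif_run(const arma::sp_mat& A, const arma::mat& U, arma::mat W,
                 double tau_m, double v_rest, double v_th, double v_reset,
                 double tau_ref, double tau_rise, double tau_decay,
                 double I_bias,
                 double dt, int n_steps,
                 arma::vec v, arma::vec r, arma::vec h, arma::vec refr,
                 double t0,
                 const arma::mat& teacher,
                 bool teacher_feedback,
                 bool train, int settle_steps, int update_every, double alpha,
                 int record_every) {
  const int N = static_cast<int>(v.n_elem);
  const int M = static_cast<int>(U.n_cols);
  const double ed = std::exp(-dt / tau_decay);
  const double er = std::exp(-dt / tau_rise);
  // exact propagator coupling h(t) into r(t + dt)
  const double cr = (er - ed) * tau_decay * tau_rise / (tau_rise - tau_decay);
  const double h_inc = 1.0 / (tau_rise * tau_decay);

  if ((train || teacher_feedback) &&
      (static_cast<int>(teacher.n_rows) < n_steps ||
       static_cast<int>(teacher.n_cols) != M))
    stop("teacher matrix must be n_steps x M");

  arma::mat P;
  if (train) P = arma::eye(N, N) / alpha;

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(4096);
  spike_t.reserve(4096);

  int n_rec = (record_every > 0) ? (n_steps + record_every - 1) / record_every
                                 : 0;
  arma::mat z_trace(n_rec, M, arma::fill::zeros);
  arma::vec t_trace(n_rec, arma::fill::zeros);
  std::vector<double> err_t, err_rmse;

  int rec = 0;
  arma::vec zhat(M), Isyn(N), fb(M), e(M), Pr(N);

  for (int s = 0; s < n_steps; ++s) {
    zhat = W * r;
    if (teacher_feedback)
      fb = teacher.row(s).t();
    else
      fb = zhat;
    Isyn = A * r + U * fb;

    if (record_every > 0 && s % record_every == 0) {
      t_trace(rec) = t0 + s * dt;
      z_trace.row(rec) = zhat.t();
      ++rec;
    }

    // voltage update / refractory clamp
    for (int i = 0; i < N; ++i) {
      if (refr(i) > 0.0) {
        refr(i) -= dt;
        v(i) = v_reset;
      } else {
        v(i) += dt / tau_m * (v_rest - v(i) + I_bias + Isyn(i));
      }
    }

    // exact exponential update of the synaptic pair (uses h at step start)
    r = r * ed + h * cr;
    h *= er;

    // threshold, reset, refractory freeze; spike time at end of step
    const double t_spk = t0 + (s + 1) * dt;
    for (int i = 0; i < N; ++i) {
      if (refr(i) <= 0.0 && v(i) >= v_th) {
        spike_id.push_back(i);
        spike_t.push_back(t_spk);
        v(i) = v_reset;
        refr(i) = tau_ref;
        h(i) += h_inc;
      }
    }

    if (train && s >= settle_steps && (s + 1) % update_every == 0) {
      e = W * r - teacher.row(s).t();
      Pr = P * r;
      double rPr = arma::dot(r, Pr);
      P -= (Pr * Pr.t()) / (1.0 + rPr);
      P = 0.5 * (P + P.t());
      Pr = P * r;
      W -= e * Pr.t();
      err_t.push_back(t0 + (s + 1) * dt);
      err_rmse.push_back(std::sqrt(arma::mean(arma::square(e))));
    }

    if (s % 400 == 0 && !v.is_finite())
      stop("non-finite membrane potential at t = %f s; the simulation is "
           "unstable (reduce dt, g, or alpha)", t0 + s * dt);
  }

  if (!v.is_finite() || !r.is_finite())
    stop("non-finite state at end of run; the simulation is unstable "
         "(reduce dt, g, or alpha)");

  return List::create(
      _["spike_id"] = wrap(spike_id), _["spike_t"] = wrap(spike_t),
      _["t_trace"] = t_trace, _["z_trace"] = z_trace, _["W"] = W,
      _["v"] = v, _["r"] = r, _["h"] = h, _["refr"] = refr,
      _["t_end"] = t0 + n_steps * dt,
      _["err_t"] = wrap(err_t), _["err_rmse"] = wrap(err_rmse));
}
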