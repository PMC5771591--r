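#include <Rcpp.h>
#include "model.h"

using namespace Rcpp;
using namespace cmef;

static void check_lengths(const NumericVector& state, const NumericVector& par) {
  if (state.size() != N_STATE) stop("cell state must have %d entries", N_STATE);
  if (par.size() != N_PAR) stop("cell parameter vector must have %d entries", N_PAR);
}

// [[Rcpp::export]]
NumericVector cpp_cell_currents(NumericVector state, NumericVector par,
                                double isac) {
  check_lengths(state, par);
  double cur[N_CUR];
  tnnp_currents(REAL(state), REAL(par), isac, cur);
  NumericVector out(N_CUR);
  for (int i = 0; i < N_CUR; ++i) out[i] = cur[i];
  out.attr("names") = CharacterVector::create(
      "i_na", "i_nak", "i_bna", "i_k1", "i_to", "i_kr", "i_ks", "i_pk",
      "i_cal", "i_naca", "i_pca", "i_bca", "i_sac", "i_total");
  return out;
}

// [[Rcpp::export]]
List cpp_cell_step(NumericVector state, NumericVector par, double istim,
                   double isac, double dt) {
  check_lengths(state, par);
  NumericVector s = clone(state);
  double cur[N_CUR];
  int rc = tnnp_step(REAL(s), REAL(par), istim, isac, dt, cur);
  NumericVector cv(N_CUR);
  for (int i = 0; i < N_CUR; ++i) cv[i] = cur[i];
  return List::create(_["state"] = s, _["status"] = rc, _["currents"] = cv);
}

// Run a cell with a (possibly periodic) rectangular stimulus and a fixed
// stretch ratio.  Returns sampled time/vm/cai (+ optionally full state
// snapshots) and the final state.
// sac = {g_sac, v_rev, k, alpha} or length 0 to disable.
// stim = {amplitude, onset, duration, period (<=0 for single pulse)}
// [[Rcpp::export]]
List cpp_run_cell(NumericVector state, NumericVector par, NumericVector sac,
                  double lambda, NumericVector stim, double duration,
                  double dt, double stride, bool full_states = false) {
  check_lengths(state, par);
  if (dt <= 0) stop("dt must be positive");
  if (stride < dt) stride = dt;
  NumericVector s = clone(state);
  double* S = REAL(s);
  const double* P = REAL(par);
  const bool has_sac = sac.size() >= 4 && sac[0] > 0;
  double sacp[4] = {0, 0, 0, 0};
  if (sac.size() >= 4) for (int i = 0; i < 4; ++i) sacp[i] = sac[i];

  const double amp = stim.size() > 0 ? stim[0] : 0.0;
  const double onset = stim.size() > 1 ? stim[1] : 0.0;
  const double sdur = stim.size() > 2 ? stim[2] : 0.0;
  const double period = stim.size() > 3 ? stim[3] : -1.0;

  const long nstep = (long)std::llround(duration / dt);
  const long samp_every = (long)std::llround(stride / dt);
  const long nout = nstep / samp_every + 1;

  NumericVector t_out(nout), vm_out(nout), cai_out(nout);
  NumericMatrix st_out = full_states ? NumericMatrix(nout, N_STATE)
                                     : NumericMatrix(1, 1);
  long k = 0;
  for (long i = 0; i <= nstep; ++i) {
    const double t = i * dt;
    if (i % samp_every == 0 && k < nout) {
      t_out[k] = t; vm_out[k] = S[iV]; cai_out[k] = S[iCAI];
      if (full_states) for (int j = 0; j < N_STATE; ++j) st_out(k, j) = S[j];
      ++k;
    }
    if (i == nstep) break;
    double istim = 0.0;
    if (amp != 0.0 && sdur > 0.0) {
      double tt = t - onset;
      if (period > 0.0 && tt >= 0.0) tt -= period * std::floor(tt / period);
      if (tt >= 0.0 && tt < sdur) istim = amp;
    }
    const double isac = has_sac ? sac_current(S[iV], lambda, sacp) : 0.0;
    int rc = tnnp_step(S, P, istim, isac, dt);
    if (rc != 0)
      stop("numerical instability in cell integration at t = %.3f ms "
           "(dt = %g ms, code %d); reduce dt", t, dt, rc);
  }
  List out = List::create(_["time"] = t_out, _["vm"] = vm_out,
                          _["cai"] = cai_out, _["final_state"] = s);
  if (full_states) out["states"] = st_out;
  return out;
}

// Quiescent or paced equilibration; returns only the final state.
// [[Rcpp::export]]
NumericVector cpp_equilibrate_cell(NumericVector state, NumericVector par,
                                   NumericVector sac, double lambda,
                                   NumericVector stim, double duration,
                                   double dt) {
  List r = cpp_run_cell(state, par, sac, lambda, stim, duration, dt,
                        duration, false);
  return r["final_state"];
}
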