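#include <Rcpp.h>
#include "model.h"

using namespace Rcpp;
using namespace cmef;

// [[Rcpp::export]]
List cpp_nl_step(NumericVector state, double cai, NumericVector par,
                 double dt, int mode, double aux) {
  if (state.size() != N_NL) stop("sarcomere state must have %d entries", N_NL);
  if (par.size() != N_NLPAR) stop("sarcomere parameter vector must have %d entries", N_NLPAR);
  NumericVector s = clone(state);
  int rc = nl_step(REAL(s), cai, REAL(par), dt, mode, aux);
  double fa = nl_active_force(REAL(s), REAL(par));
  double fp = nl_passive_force(s[nL], REAL(par));
  return List::create(_["state"] = s, _["status"] = rc,
                      _["force"] = fa, _["passive_force"] = fp);
}

// Drive the myofilament model with a uniformly sampled calcium trace.
// mode 0: isometric at the initial length; mode 2: prescribed length
// trajectory `len` (same length as cai).  `substeps` forward-Euler substeps
// per calcium sample.
// [[Rcpp::export]]
List cpp_nl_run(NumericVector state, NumericVector cai, NumericVector par,
                double dt_sample, int mode, NumericVector len, int substeps) {
  if (state.size() != N_NL) stop("sarcomere state must have %d entries", N_NL);
  if (par.size() != N_NLPAR) stop("sarcomere parameter vector must have %d entries", N_NLPAR);
  if (substeps < 1) substeps = 1;
  const int n = cai.size();
  if (mode == 2 && len.size() != n)
    stop("prescribed-length mode needs one length per calcium sample");
  NumericVector s = clone(state);
  double* S = REAL(s);
  const double* q = REAL(par);
  const double dt = dt_sample / substeps;

  NumericVector force(n), half_sl(n), passive(n);
  for (int i = 0; i < n; ++i) {
    const double aux = (mode == 2) ? len[i] : (mode == 1 ? len[0] : 0.0);
    if (i > 0) {
      for (int k = 0; k < substeps; ++k) {
        int rc = nl_step(S, cai[i], q, dt, mode, aux);
        if (rc != 0)
          stop("myofilament integration unstable at sample %d (code %d); "
               "reduce dt", i, rc);
      }
    } else if (mode == 2) {
      S[nL] = aux;
    }
    force[i] = nl_active_force(S, q);
    passive[i] = nl_passive_force(S[nL], q);
    half_sl[i] = S[nL];
  }
  return List::create(_["force"] = force, _["half_sl"] = half_sl,
                      _["passive_force"] = passive, _["final_state"] = s);
}
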