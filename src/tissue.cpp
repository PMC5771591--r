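#include <Rcpp.h>
#include "model.h"
#include <vector>

using namespace Rcpp;
using namespace cmef;

// Explicit diffusion steps on the ring-lattice geometry (shared with the
// coupled simulator): nodes indexed ring-major; closed rings, no-flux at
// apex/base.  g_ring: per-ring neighbour coupling (1/ms); g_ax: per-interface
// coupling between ring r and r+1 (1/ms).
// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector field, int n_rings, int npr,
                          NumericVector g_ring, NumericVector g_ax,
                          double dt, int nsteps) {
  if ((int)field.size() != n_rings * npr) stop("field length != n_rings * nodes_per_ring");
  if ((int)g_ring.size() != n_rings) stop("g_ring must have one entry per ring");
  if ((int)g_ax.size() != std::max(n_rings - 1, 0)) stop("g_ax must have n_rings - 1 entries");
  std::vector<double> v(field.begin(), field.end());
  std::vector<double> lap(v.size());
  for (int s = 0; s < nsteps; ++s) {
    for (int r = 0; r < n_rings; ++r) {
      const double gr = g_ring[r];
      const double gdn = r > 0 ? g_ax[r - 1] : 0.0;
      const double gup = r < n_rings - 1 ? g_ax[r] : 0.0;
      for (int k = 0; k < npr; ++k) {
        const int i = r * npr + k;
        const int il = r * npr + (k + npr - 1) % npr;
        const int ir = r * npr + (k + 1) % npr;
        double acc = gr * (v[il] + v[ir] - 2.0 * v[i]);
        if (gdn > 0.0) acc += gdn * (v[i - npr] - v[i]);
        if (gup > 0.0) acc += gup * (v[i + npr] - v[i]);
        lap[i] = acc;
      }
    }
    for (size_t i = 0; i < v.size(); ++i) v[i] += dt * lap[i];
  }
  return NumericVector(v.begin(), v.end());
}

// ---------------------------------------------------------------------------
// Coupled ventricle simulator: monodomain electrics + per-node myofilament +
// ring mechanics + lumped haemodynamics (resistive valves, 2-element
// Windkessel afterload), with the geometry -> half-sarcomere-length ->
// stretch-ratio -> I_SAC feedback applied one step lagged.
//
// mech = {kact, kpass, beta_p, p_fill, r_av, r_per, c_art, part0, r_fill,
//         kappa, tau_delta}
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_ventricle(int n_rings, int npr,
                       NumericVector r0,          // unstressed ring radii, mm
                       NumericVector dz,          // ring axial extents, mm
                       double half_sl0,           // um
                       double v0,                 // unstressed cavity volume, mL
                       NumericVector g_ring, NumericVector g_ax,
                       NumericVector cell_state0, NumericVector cell_par,
                       NumericVector sac, NumericVector nl_state0,
                       NumericVector nl_par, NumericVector mech,
                       double preload,            // initial stretch ratio
                       double stim_amp, double stim_onset, double stim_dur,
                       IntegerVector stim_nodes,  // 0-based node indices
                       double duration, double dt, double stride,
                       bool freeze_geometry) {
  const int nnode = n_rings * npr;
  if ((int)r0.size() != n_rings || (int)dz.size() != n_rings)
    stop("geometry vectors must have one entry per ring");
  if (cell_state0.size() != N_STATE || nl_state0.size() != N_NL ||
      cell_par.size() != N_PAR || nl_par.size() != N_NLPAR)
    stop("bad state/parameter vector length");
  if (mech.size() < 11) stop("mechanics parameter vector must have 11 entries");
  if (dt <= 0) stop("dt must be positive");

  // CFL bound for the explicit diffusion update
  double worst = 0.0;
  for (int r = 0; r < n_rings; ++r) {
    double tot = 2.0 * g_ring[r];
    if (r > 0) tot += g_ax[r - 1];
    if (r < n_rings - 1) tot += g_ax[r];
    if (tot > worst) worst = tot;
  }
  if (dt * worst >= 1.0)
    stop("explicit diffusion unstable: dt * max coupling = %.3f >= 1; "
         "use dt < %.5f ms", dt * worst, 1.0 / worst);

  const double kact = mech[0], kpass = mech[1], beta_p = mech[2];
  const double p_fill = mech[3], r_av = mech[4], r_per = mech[5];
  const double c_art = mech[6];
  const double r_fill = mech[8], kappa = mech[9], tau_delta = mech[10];

  const bool has_sac = sac.size() >= 4 && sac[0] > 0;
  double sacp[4] = {0, 0, 0, 0};
  if (sac.size() >= 4) for (int i = 0; i < 4; ++i) sacp[i] = sac[i];

  // state arrays
  std::vector<double> cell(nnode * N_STATE), nls(nnode * N_NL);
  for (int i = 0; i < nnode; ++i) {
    for (int j = 0; j < N_STATE; ++j) cell[i * N_STATE + j] = cell_state0[j];
    for (int j = 0; j < N_NL; ++j) nls[i * N_NL + j] = nl_state0[j];
  }
  std::vector<double> lam(n_rings, preload), delta(n_rings, 0.0);
  std::vector<double> fbar(n_rings, 0.0), lap(nnode, 0.0);
  std::vector<bool> is_stim(nnode, false);
  for (int i = 0; i < stim_nodes.size(); ++i) {
    if (stim_nodes[i] < 0 || stim_nodes[i] >= nnode) stop("stimulus node out of range");
    is_stim[stim_nodes[i]] = true;
  }
  for (int i = 0; i < nnode; ++i)
    nls[i * N_NL + nL] = preload * half_sl0;  // stretched diastolic length

  double vol = preload * preload * v0;
  double s_scale = preload;
  double part = mech[7];

  // volume weights for the zero-mean constraint on the redistribution field
  std::vector<double> uw(n_rings);
  double uw_sum = 0.0, dz_sum = 0.0;
  for (int r = 0; r < n_rings; ++r) {
    uw[r] = dz[r] * r0[r] * r0[r];
    uw_sum += uw[r];
    dz_sum += dz[r];
  }

  const long nstep = (long)std::llround(duration / dt);
  long samp_every = (long)std::llround(stride / dt);
  if (samp_every < 1) samp_every = 1;
  const long nout = nstep / samp_every + 1;

  NumericMatrix vm_out(nout, nnode), lam_out(nout, n_rings),
      f_out(nout, n_rings);
  NumericVector t_out(nout), vol_out(nout), p_out(nout), part_out(nout);

  double pressure = 0.0;
  long k = 0;
  for (long istep = 0; istep <= nstep; ++istep) {
    const double t = istep * dt;

    // ring mechanics state derived from current forces
    double tbar = 0.0, psum = 0.0;
    for (int r = 0; r < n_rings; ++r) {
      double acc = 0.0;
      for (int kk = 0; kk < npr; ++kk)
        acc += nl_active_force(&nls[(r * npr + kk) * N_NL], REAL(nl_par));
      fbar[r] = acc / npr;
      tbar += kact * fbar[r] / n_rings;
    }
    for (int r = 0; r < n_rings; ++r) {
      const double tension = kact * fbar[r] +
                             kpass * (std::exp(beta_p * (lam[r] - 1.0)) - 1.0);
      psum += dz[r] * tension / (lam[r] * r0[r]);
    }
    pressure = psum / dz_sum;

    if (istep % samp_every == 0 && k < nout) {
      t_out[k] = t; vol_out[k] = vol; p_out[k] = pressure; part_out[k] = part;
      for (int i = 0; i < nnode; ++i) vm_out(k, i) = cell[i * N_STATE + iV];
      for (int r = 0; r < n_rings; ++r) {
        lam_out(k, r) = lam[r];
        f_out(k, r) = fbar[r];
      }
      ++k;
    }
    if (istep == nstep) break;

    // --- electrics: diffusion (from current field) + reaction ---
    for (int r = 0; r < n_rings; ++r) {
      const double gr = g_ring[r];
      const double gdn = r > 0 ? g_ax[r - 1] : 0.0;
      const double gup = r < n_rings - 1 ? g_ax[r] : 0.0;
      for (int kk = 0; kk < npr; ++kk) {
        const int i = r * npr + kk;
        const int il = r * npr + (kk + npr - 1) % npr;
        const int ir = r * npr + (kk + 1) % npr;
        double acc = gr * (cell[il * N_STATE + iV] + cell[ir * N_STATE + iV] -
                           2.0 * cell[i * N_STATE + iV]);
        if (gdn > 0.0) acc += gdn * (cell[(i - npr) * N_STATE + iV] -
                                     cell[i * N_STATE + iV]);
        if (gup > 0.0) acc += gup * (cell[(i + npr) * N_STATE + iV] -
                                     cell[i * N_STATE + iV]);
        lap[i] = acc;
      }
    }
    const bool stim_on = stim_amp != 0.0 && t >= stim_onset &&
                         t < stim_onset + stim_dur;
    for (int r = 0; r < n_rings; ++r) {
      const double isac_base = has_sac ? 1.0 : 0.0;
      for (int kk = 0; kk < npr; ++kk) {
        const int i = r * npr + kk;
        double* S = &cell[i * N_STATE];
        const double isac = isac_base != 0.0
                                ? sac_current(S[iV], lam[r], sacp)
                                : 0.0;
        const double istim = (stim_on && is_stim[i]) ? stim_amp : 0.0;
        int rc = tnnp_step(S, REAL(cell_par), istim, isac, dt);
        if (rc != 0)
          stop("tissue electrophysiology unstable at t = %.2f ms, node %d "
               "(code %d)", t, i + 1, rc);
        S[iV] += dt * lap[i];
        // myofilament: half-sarcomere length prescribed by ring kinematics
        int rn = nl_step(&nls[i * N_NL], S[iCAI], REAL(nl_par), dt, 2,
                         lam[r] * half_sl0);
        if (rn != 0)
          stop("myofilament unstable at t = %.2f ms, node %d (code %d)",
               t, i + 1, rn);
      }
    }

    if (!freeze_geometry) {
      // --- haemodynamics: resistive valves + Windkessel afterload ---
      const double q_out = pressure > part ? (pressure - part) / r_av : 0.0;
      const double q_in = pressure < p_fill ? (p_fill - pressure) / r_fill : 0.0;
      vol += dt * (q_in - q_out);
      part += dt * (q_out - part / r_per) / c_art;
      if (vol < 0.05 * v0) vol = 0.05 * v0;
      s_scale = std::sqrt(vol / v0);

      // --- regional redistribution at constant volume ---
      if (kappa > 0.0 && kact > 0.0) {
        double mean_shift = 0.0;
        for (int r = 0; r < n_rings; ++r) {
          delta[r] += dt * (-kappa * (kact * fbar[r] - tbar) / kact -
                            delta[r] / tau_delta);
          mean_shift += uw[r] * delta[r];
        }
        mean_shift /= uw_sum;
        for (int r = 0; r < n_rings; ++r) delta[r] -= mean_shift;
      }
      for (int r = 0; r < n_rings; ++r) {
        lam[r] = s_scale * (1.0 + delta[r]);
        if (lam[r] < 0.2) lam[r] = 0.2;
      }
    }
  }

  return List::create(
      _["time"] = t_out, _["vm"] = vm_out, _["lambda"] = lam_out,
      _["force"] = f_out, _["volume"] = vol_out, _["pressure"] = p_out,
      _["p_art"] = part_out);
}
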