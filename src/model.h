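#ifndef CARDIOMEF_MODEL_H
#define CARDIOMEF_MODEL_H

#include <cmath>

// ---------------------------------------------------------------------------
// Human ventricular myocyte ionic model (ten Tusscher-Noble-Noble-Panfilov
// 2004 formulation, mid-myocardial parameter set) plus a stretch-activated
// channel current.  Voltages in mV, time in ms, concentrations in mM,
// currents in pA/pF.  Forward-Euler state update.
// ---------------------------------------------------------------------------

namespace cmef {

// state vector layout (17 entries)
enum StateIdx {
  iV = 0, iM, iH, iJ, iXR1, iXR2, iXS, iR, iS, iD, iF, iFCA, iG,
  iCAI, iCASR, iNAI, iKI, N_STATE
};

// tunable parameter layout (13 entries); everything else is a model constant
enum ParIdx {
  pGNA = 0, pGK1, pGTO, pGKR, pGKS, pGCAL, pGBNA, pGBCA, pGPK, pGPCA,
  pKNAK, pKNACA, pCM, N_PAR
};

// current record layout
enum CurIdx {
  cNA = 0, cNAK, cBNA, cK1, cTO, cKR, cKS, cPK, cCAL, cNACA, cPCA, cBCA,
  cSAC, cTOT, N_CUR
};

// physical constants and fixed model constants
const double Rgas = 8314.472;     // J/(kmol K)
const double Frd  = 96485.3415;   // C/mol
const double Tmp  = 310.0;        // K
const double RTONF = Rgas * Tmp / Frd;

const double Ko = 5.4, Cao = 2.0, Nao = 140.0;   // mM
const double Vc = 0.016404, Vsr = 0.001094;       // volumes (um^3 scale)
const double Bufc = 0.15,  Kbufc = 0.001;
const double Bufsr = 10.0, Kbufsr = 0.3;
const double Vmaxup = 0.000425, Kup = 0.00025;
const double KmK = 1.0, KmNa = 40.0;
const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, anaca = 2.5;
const double KpCa = 0.0005;
const double pKNa = 0.03;
const double arel = 0.016464, brel = 0.25, crel = 0.008232;
const double Vleak = 0.00008;
const double tau_g = 2.0, tau_fca = 2.0;

// stretch-activated channel: sac = {g_sac (nS/pF), v_rev (mV), k, alpha}
inline double sac_current(double v, double lam, const double* sac) {
  if (sac == 0 || sac[0] <= 0.0) return 0.0;
  return sac[0] * (v - sac[1]) / (1.0 + sac[2] * std::exp(-sac[3] * (lam - 1.0)));
}

// compute all membrane currents for a given state (no state change)
inline void tnnp_currents(const double* S, const double* p, double isac,
                          double* cur) {
  const double V = S[iV];
  const double Cai = S[iCAI], Nai = S[iNAI], Ki = S[iKI];

  const double Ena = RTONF * std::log(Nao / Nai);
  const double Ek  = RTONF * std::log(Ko / Ki);
  const double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  cur[cNA] = p[pGNA] * S[iM] * S[iM] * S[iM] * S[iH] * S[iJ] * (V - Ena);

  cur[cNAK] = p[pKNAK] * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
              (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
               0.0353 * std::exp(-V / RTONF));

  cur[cBNA] = p[pGBNA] * (V - Ena);

  {
    const double dv = V - Ek;
    const double ak1 = 0.1 / (1.0 + std::exp(0.06 * (dv - 200.0)));
    const double bk1 = (3.0 * std::exp(0.0002 * (dv + 100.0)) +
                        std::exp(0.1 * (dv - 10.0))) /
                       (1.0 + std::exp(-0.5 * dv));
    cur[cK1] = p[pGK1] * std::sqrt(Ko / 5.4) * (ak1 / (ak1 + bk1)) * dv;
  }

  cur[cTO] = p[pGTO] * S[iR] * S[iS] * (V - Ek);
  cur[cKR] = p[pGKR] * std::sqrt(Ko / 5.4) * S[iXR1] * S[iXR2] * (V - Ek);
  cur[cKS] = p[pGKS] * S[iXS] * S[iXS] * (V - Eks);
  cur[cPK] = p[pGPK] * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));

  {
    double z = 2.0 * V / RTONF;         // 2VF/RT
    double num, den;
    if (std::fabs(z) < 1e-7) {          // limit V -> 0 of GHK driving term
      num = Cai - 0.341 * Cao;
      den = 1.0;
      cur[cCAL] = p[pGCAL] * S[iD] * S[iF] * S[iFCA] * 2.0 * Frd * num / den;
    } else {
      const double ez = std::exp(z);
      cur[cCAL] = p[pGCAL] * S[iD] * S[iF] * S[iFCA] * 4.0 * V * Frd / RTONF *
                  (Cai * ez - 0.341 * Cao) / (ez - 1.0);
    }
  }

  {
    const double e1 = std::exp(gam * V / RTONF);
    const double e2 = std::exp((gam - 1.0) * V / RTONF);
    cur[cNACA] = p[pKNACA] *
                 (e1 * Nai * Nai * Nai * Cao -
                  e2 * Nao * Nao * Nao * Cai * anaca) /
                 ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
                  (1.0 + ksat * e2));
  }

  cur[cPCA] = p[pGPCA] * Cai / (Cai + KpCa);
  cur[cBCA] = p[pGBCA] * (V - Eca);
  cur[cSAC] = isac;

  double tot = 0.0;
  for (int i = 0; i < cTOT; ++i) tot += cur[i];
  cur[cTOT] = tot;
}

// one forward-Euler step; returns 0 on success, 1 on non-finite state,
// 2 on gate overshoot beyond tolerance.  `cur` (length N_CUR) optional.
inline int tnnp_step(double* S, const double* p, double istim, double isac,
                     double dt, double* cur_out = 0) {
  double cur[N_CUR];
  tnnp_currents(S, p, isac, cur);
  const double V = S[iV];

  // --- gate rates (2004 formulation) ---
  double inf[13], tau[13];  // indexed by gate position in state vector - 1

  // m
  {
    double m_inf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    inf[0] = m_inf; tau[0] = am * bm;
  }
  // h, j
  {
    double h_inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    inf[1] = h_inf; tau[1] = 1.0 / (ah + bh);
    inf[2] = h_inf; tau[2] = 1.0 / (aj + bj);
  }
  // xr1, xr2
  {
    inf[3] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    tau[3] = a * b;
    inf[4] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    tau[4] = a * b;
  }
  // xs
  {
    inf[5] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    double a = 1100.0 / std::sqrt(1.0 + std::exp((-10.0 - V) / 6.0));
    double b = 1.0 / (1.0 + std::exp((V - 60.0) / 20.0));
    tau[5] = a * b;
  }
  // r, s (mid-myocardial / epicardial transient-outward kinetics)
  {
    inf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    tau[6] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    inf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    tau[7] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
             5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  // d, f
  {
    inf[8] = 1.0 / (1.0 + std::exp((-5.0 - V) / 7.5));
    double a = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double b = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double c = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    tau[8] = a * b + c;
    inf[9] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    tau[9] = 1125.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) + 80.0 +
             165.0 / (1.0 + std::exp((25.0 - V) / 10.0));
  }
  // fCa (Cai-gated, with the upward-lock above -60 mV)
  const double Cai = S[iCAI];
  {
    double a = 1.0 / (1.0 + std::pow(Cai / 0.000325, 8.0));
    double b = 0.1 / (1.0 + std::exp((Cai - 0.0005) / 0.0001));
    double c = 0.2 / (1.0 + std::exp((Cai - 0.00075) / 0.0008));
    inf[10] = (a + b + c + 0.23) / 1.46;
    tau[10] = tau_fca;
  }
  // g (SR release gate, same locking rule)
  {
    double g_inf;
    if (Cai <= 0.00035)
      g_inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 6.0));
    else
      g_inf = 1.0 / (1.0 + std::pow(Cai / 0.00035, 16.0));
    inf[11] = g_inf; tau[11] = tau_g;
  }

  // --- advance gates (Rush-Larsen exponential update; exact for the
  // locally linearized gate equation and stable at dt = 0.02 ms, where a
  // plain Euler update of the fast m gate, tau ~ 1e-3 ms, would blow up) ---
  for (int k = 0; k < 12; ++k) {
    const int si = 1 + k;  // gates occupy state slots 1..12
    if (k == 10 || k == 11) {       // fCa and g: locked while depolarized
      if (inf[k] > S[si] && V > -60.0) continue;
    }
    double gnew = inf[k] - (inf[k] - S[si]) * std::exp(-dt / tau[k]);
    // fCa is a scaling factor whose steady state exceeds 1 at low Cai
    // (up to (1 + 0.1 + 0.2 + 0.23)/1.46); only its lower bound is a
    // hard constraint.
    const double upper = (k == 10) ? 1.53 / 1.46 : 1.0;
    if (gnew < 0.0) {
      if (gnew < -1e-9) return 2;
      gnew = 0.0;
    } else if (gnew > upper) {
      if (gnew > upper + 1e-9) return 2;
      gnew = upper;
    }
    S[si] = gnew;
  }

  // --- intracellular ion dynamics (rapid-buffering algebraic update) ---
  const double Cm = p[pCM];
  const double invVcF2 = 1.0 / (2.0 * Vc * Frd);
  const double invVcF  = 1.0 / (Vc * Frd);

  const double CaSR = S[iCASR];
  const double Irel = (arel * CaSR * CaSR / (brel * brel + CaSR * CaSR) + crel) *
                      S[iD] * S[iG];
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));

  const double CaCurrent =
      -(cur[cCAL] + cur[cBCA] + cur[cPCA] - 2.0 * cur[cNACA]) * invVcF2 * Cm;
  const double CaSRCurrent = Iup - Irel - Ileak;

  {
    const double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
    const double dCaSR = dt * (Vc / Vsr) * CaSRCurrent;
    const double b = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
    const double c = Kbufsr * (CaCSQN + dCaSR + CaSR);
    S[iCASR] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  {
    const double CaBuf = Bufc * Cai / (Cai + Kbufc);
    const double dCai = dt * (CaCurrent - CaSRCurrent);
    const double b = Bufc - CaBuf - dCai - Cai + Kbufc;
    const double c = Kbufc * (CaBuf + dCai + Cai);
    S[iCAI] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }

  S[iNAI] += -dt * (cur[cNA] + cur[cBNA] + 3.0 * cur[cNAK] + 3.0 * cur[cNACA]) *
             invVcF * Cm;
  // stimulus charge is carried by K+ (positive istim depolarizes)
  S[iKI] += -dt * (cur[cK1] + cur[cTO] + cur[cKR] + cur[cKS] -
                   2.0 * cur[cNAK] + cur[cPK] - istim) * invVcF * Cm;

  // --- membrane voltage ---
  S[iV] = V - dt * (cur[cTOT] - istim);

  for (int i = 0; i < N_STATE; ++i)
    if (!std::isfinite(S[i])) return 1;
  if (cur_out) for (int i = 0; i < N_CUR; ++i) cur_out[i] = cur[i];
  return 0;
}

// ---------------------------------------------------------------------------
// Negroni-Lascano style four-state myofilament model.
// States: L (half-sarcomere length, um), X (crossbridge anchor, um),
// TSCa3, TSCa3s (attached, Ca-bound), TSs (attached, Ca-free) in uM.
// Calcium input in mM (converted to uM internally).
// ---------------------------------------------------------------------------

enum NlStateIdx { nL = 0, nX, nTSCA3, nTSCA3S, nTSS, N_NL };

enum NlParIdx {
  qTT = 0, qY1, qZ1, qY2, qZ2, qY3, qZ3, qY4, qB, qHC, qA,
  qLA, qLOPT, qKP, qBETAP, qL0, N_NLPAR
};

inline double nl_overlap(double L, const double* q) {
  double w = (L - q[qLA]) / (q[qLOPT] - q[qLA]);
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
  return w;
}

inline double nl_active_force(const double* S, const double* q) {
  double h = S[nL] - S[nX];
  double f = q[qA] * h * (S[nTSCA3S] + S[nTSS]) * nl_overlap(S[nL], q);
  return f;
}

inline double nl_passive_force(double L, const double* q) {
  return q[qKP] * (std::exp(q[qBETAP] * (L - q[qL0])) - 1.0);
}

// mode: 0 isometric (L held), 1 isotonic against `aux`=load (normalized
// force units, viscous length dynamics), 2 prescribed length (`aux`=L target)
inline int nl_step(double* S, double cai_mM, const double* q, double dt,
                   int mode, double aux) {
  const double ca = cai_mM * 1000.0;      // uM
  const double ca3 = ca * ca * ca;
  const double TS = q[qTT] - S[nTSCA3] - S[nTSCA3S] - S[nTSS];

  const double dTSCa3 = q[qY1] * ca3 * TS - q[qZ1] * S[nTSCA3] -
                        q[qY2] * S[nTSCA3] + q[qZ2] * S[nTSCA3S];
  const double dTSCa3s = q[qY2] * S[nTSCA3] - q[qZ2] * S[nTSCA3S] -
                         q[qY3] * S[nTSCA3S] + q[qZ3] * ca3 * S[nTSS];
  const double dTSs = q[qY3] * S[nTSCA3S] - q[qZ3] * ca3 * S[nTSS] -
                      q[qY4] * S[nTSS];

  S[nTSCA3]  += dt * dTSCa3;
  S[nTSCA3S] += dt * dTSCa3s;
  S[nTSS]    += dt * dTSs;
  if (S[nTSCA3] < 0.0 || S[nTSCA3S] < 0.0 || S[nTSS] < 0.0) {
    // forward-Euler undershoot of a small positive pool: clip tiny overshoot
    if (S[nTSCA3] < -1e-6 || S[nTSCA3S] < -1e-6 || S[nTSS] < -1e-6) return 3;
    if (S[nTSCA3] < 0.0) S[nTSCA3] = 0.0;
    if (S[nTSCA3S] < 0.0) S[nTSCA3S] = 0.0;
    if (S[nTSS] < 0.0) S[nTSS] = 0.0;
  }

  // length dynamics
  if (mode == 2) {
    S[nL] = aux;
  } else if (mode == 1) {
    const double ftot = nl_active_force(S, q) + nl_passive_force(S[nL], q);
    const double mu = 50.0;  // viscous constant, ms per unit normalized force
    S[nL] += dt * (aux - ftot) / mu;
    if (S[nL] < 0.5 * q[qL0]) S[nL] = 0.5 * q[qL0];
  }
  // crossbridge anchor slides toward elongation hc
  S[nX] += dt * q[qB] * (S[nL] - S[nX] - q[qHC]);

  for (int i = 0; i < N_NL; ++i)
    if (!std::isfinite(S[i])) return 1;
  return 0;
}

}  // namespace cmef

#endif
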