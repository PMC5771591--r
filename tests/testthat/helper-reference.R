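# Independent pure-R reference implementation of the mid-myocardial
# ventricular ionic model used as an oracle for the compiled core: one
# integration step (Rush-Larsen gates, forward-Euler voltage and
# concentrations) written directly from the published formulation,
# sharing no code with src/.

ref_constants <- list(
  R = 8314.472, Temp = 310, Frd = 96485.3415,
  Ko = 5.4, Cao = 2.0, Nao = 140.0,
  Vc = 0.016404, Vsr = 0.001094,
  Bufc = 0.15, Kbufc = 0.001, Bufsr = 10, Kbufsr = 0.3,
  Vmaxup = 0.000425, Kup = 0.00025,
  KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35, anaca = 2.5,
  pKNa = 0.03, KmK = 1.0, KmNa = 40.0,
  KpCa = 0.0005,
  arel = 0.016464, brel = 0.25, crel = 0.008232, Vleak = 8e-5,
  tau_g = 2, tau_fca = 2
)

ref_currents <- function(s, p, isac = 0) {
  k <- ref_constants
  rtf <- k$R * k$Temp / k$Frd
  V <- s[["vm"]]
  Ek <- rtf * log(k$Ko / s[["ki"]])
  Ena <- rtf * log(k$Nao / s[["nai"]])
  Eks <- rtf * log((k$Ko + k$pKNa * k$Nao) / (s[["ki"]] + k$pKNa * s[["nai"]]))
  Eca <- 0.5 * rtf * log(k$Cao / s[["cai"]])

  ak1 <- 0.1 / (1 + exp(0.06 * (V - Ek - 200)))
  bk1 <- (3 * exp(0.0002 * (V - Ek + 100)) + exp(0.1 * (V - Ek - 10))) /
    (1 + exp(-0.5 * (V - Ek)))
  xk1 <- ak1 / (ak1 + bk1)

  i_na <- p$g_na * s[["m"]]^3 * s[["h"]] * s[["j"]] * (V - Ena)
  i_k1 <- p$g_k1 * sqrt(k$Ko / 5.4) * xk1 * (V - Ek)
  i_to <- p$g_to * s[["r"]] * s[["s"]] * (V - Ek)
  i_kr <- p$g_kr * sqrt(k$Ko / 5.4) * s[["xr1"]] * s[["xr2"]] * (V - Ek)
  i_ks <- p$g_ks * s[["xs"]]^2 * (V - Eks)

  vf_rt <- V * k$Frd / (k$R * k$Temp)
  z <- 2 * vf_rt
  if (abs(z) < 1e-6) {
    # z -> 0 limit of the constant-field flux expression
    i_cal <- p$g_cal * s[["d"]] * s[["f"]] * s[["fca"]] * 2 * k$Frd *
      (s[["cai"]] - 0.341 * k$Cao)
  } else {
    i_cal <- p$g_cal * s[["d"]] * s[["f"]] * s[["fca"]] * 4 * vf_rt * k$Frd *
      (s[["cai"]] * exp(z) - 0.341 * k$Cao) / (exp(z) - 1)
  }

  i_naca <- p$k_naca *
    (exp(k$gam * vf_rt) * s[["nai"]]^3 * k$Cao -
       exp((k$gam - 1) * vf_rt) * k$Nao^3 * s[["cai"]] * k$anaca) /
    ((k$KmNai^3 + k$Nao^3) * (k$KmCa + k$Cao) *
       (1 + k$ksat * exp((k$gam - 1) * vf_rt)))
  i_nak <- p$k_nak * k$Ko * s[["nai"]] /
    ((k$Ko + k$KmK) * (s[["nai"]] + k$KmNa)) /
    (1 + 0.1245 * exp(-0.1 * vf_rt) + 0.0353 * exp(-vf_rt))
  i_pca <- p$g_pca * s[["cai"]] / (s[["cai"]] + k$KpCa)
  i_pk <- p$g_pk * (V - Ek) / (1 + exp((25 - V) / 5.98))
  i_bna <- p$g_bna * (V - Ena)
  i_bca <- p$g_bca * (V - Eca)

  total <- i_na + i_nak + i_bna + i_k1 + i_to + i_kr + i_ks + i_pk +
    i_cal + i_naca + i_pca + i_bca + isac
  c(i_na = i_na, i_nak = i_nak, i_bna = i_bna, i_k1 = i_k1, i_to = i_to,
    i_kr = i_kr, i_ks = i_ks, i_pk = i_pk, i_cal = i_cal, i_naca = i_naca,
    i_pca = i_pca, i_bca = i_bca, i_sac = isac, i_total = total)
}

ref_step <- function(s, p, istim = 0, isac = 0, dt = 0.02) {
  k <- ref_constants
  cur <- ref_currents(s, p, isac)
  V <- s[["vm"]]
  cai <- s[["cai"]]

  rl <- function(x, inf, tau) inf - (inf - x) * exp(-dt / tau)

  m_inf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  tau_m <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  h_inf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) {
    ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
    aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  xr1_inf <- 1 / (1 + exp((-26 - V) / 7))
  tau_xr1 <- (450 / (1 + exp((-45 - V) / 10))) * (6 / (1 + exp((V + 30) / 11.5)))
  xr2_inf <- 1 / (1 + exp((V + 88) / 24))
  tau_xr2 <- (3 / (1 + exp((-60 - V) / 20))) * (1.12 / (1 + exp((V - 60) / 20)))
  xs_inf <- 1 / (1 + exp((-5 - V) / 14))
  tau_xs <- (1100 / sqrt(1 + exp((-10 - V) / 6))) *
    (1 / (1 + exp((V - 60) / 20)))
  r_inf <- 1 / (1 + exp((20 - V) / 6))
  tau_r <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  s_inf <- 1 / (1 + exp((V + 20) / 5))
  tau_s <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  d_inf <- 1 / (1 + exp((-5 - V) / 7.5))
  tau_d <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  f_inf <- 1 / (1 + exp((V + 20) / 7))
  tau_f <- 1125 * exp(-(V + 27)^2 / 240) + 80 + 165 / (1 + exp((25 - V) / 10))
  fca_inf <- (1 / (1 + (cai / 0.000325)^8) +
                0.1 / (1 + exp((cai - 0.0005) / 0.0001)) +
                0.2 / (1 + exp((cai - 0.00075) / 0.0008)) + 0.23) / 1.46
  g_inf <- if (cai <= 0.00035) 1 / (1 + (cai / 0.00035)^6)
           else 1 / (1 + (cai / 0.00035)^16)

  out <- s
  out[["m"]] <- rl(s[["m"]], m_inf, tau_m)
  out[["h"]] <- rl(s[["h"]], h_inf, 1 / (ah + bh))
  out[["j"]] <- rl(s[["j"]], h_inf, 1 / (aj + bj))
  out[["xr1"]] <- rl(s[["xr1"]], xr1_inf, tau_xr1)
  out[["xr2"]] <- rl(s[["xr2"]], xr2_inf, tau_xr2)
  out[["xs"]] <- rl(s[["xs"]], xs_inf, tau_xs)
  out[["r"]] <- rl(s[["r"]], r_inf, tau_r)
  out[["s"]] <- rl(s[["s"]], s_inf, tau_s)
  out[["d"]] <- rl(s[["d"]], d_inf, tau_d)
  out[["f"]] <- rl(s[["f"]], f_inf, tau_f)
  if (!(fca_inf > s[["fca"]] && V > -60)) {
    out[["fca"]] <- rl(s[["fca"]], fca_inf, k$tau_fca)
  }
  if (!(g_inf > s[["g"]] && V > -60)) {
    out[["g"]] <- rl(s[["g"]], g_inf, k$tau_g)
  }

  Cm <- p$cm
  invVcF2 <- 1 / (2 * k$Vc * k$Frd)
  invVcF <- 1 / (k$Vc * k$Frd)
  casr <- s[["ca_sr"]]
  Irel <- (k$arel * casr^2 / (k$brel^2 + casr^2) + k$crel) *
    s[["d"]] * s[["g"]]
  Ileak <- k$Vleak * (casr - cai)
  Iup <- k$Vmaxup / (1 + k$Kup^2 / cai^2)
  CaCurrent <- -(cur[["i_cal"]] + cur[["i_bca"]] + cur[["i_pca"]] -
                   2 * cur[["i_naca"]]) * invVcF2 * Cm
  CaSRCurrent <- Iup - Irel - Ileak

  CaCSQN <- k$Bufsr * casr / (casr + k$Kbufsr)
  dCaSR <- dt * (k$Vc / k$Vsr) * CaSRCurrent
  b <- k$Bufsr - CaCSQN - dCaSR - casr + k$Kbufsr
  cc <- k$Kbufsr * (CaCSQN + dCaSR + casr)
  out[["ca_sr"]] <- (sqrt(b^2 + 4 * cc) - b) / 2

  CaBuf <- k$Bufc * cai / (cai + k$Kbufc)
  dCai <- dt * (CaCurrent - CaSRCurrent)
  b <- k$Bufc - CaBuf - dCai - cai + k$Kbufc
  cc <- k$Kbufc * (CaBuf + dCai + cai)
  out[["cai"]] <- (sqrt(b^2 + 4 * cc) - b) / 2

  out[["nai"]] <- s[["nai"]] -
    dt * (cur[["i_na"]] + cur[["i_bna"]] + 3 * cur[["i_nak"]] +
            3 * cur[["i_naca"]]) * invVcF * Cm
  out[["ki"]] <- s[["ki"]] -
    dt * (cur[["i_k1"]] + cur[["i_to"]] + cur[["i_kr"]] + cur[["i_ks"]] -
            2 * cur[["i_nak"]] + cur[["i_pk"]] - istim) * invVcF * Cm

  out[["vm"]] <- V - dt * (cur[["i_total"]] - istim)
  out
}

# short reference run (single pulse at t = 0)
ref_run <- function(state, p, amp = 52, stim_dur = 1, duration = 400,
                    dt = 0.02, stride = 0.5) {
  s <- unclass(state)
  nstep <- round(duration / dt)
  every <- round(stride / dt)
  tt <- numeric(0); vv <- numeric(0)
  for (i in 0:nstep) {
    if (i %% every == 0) { tt <- c(tt, i * dt); vv <- c(vv, s[["vm"]]) }
    if (i == nstep) break
    t <- i * dt
    istim <- if (t >= 0 && t < stim_dur) amp else 0
    s <- ref_step(s, p, istim = istim, dt = dt)
  }
  data.frame(time = tt, vm = vv)
}
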