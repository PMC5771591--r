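---
title: "Model formulation and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model formulation and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`cardiomef` simulates mechano-electric feedback (MEF) in a contracting
left ventricle: mechanical stretch feeds back on the electrics through a
stretch-activated channel (SAC) current, while the electrics drive
contraction through the calcium transient. This vignette documents the
four model layers, the numerical schemes, the calibration procedure for
the two tissue-level free constants, and the model's known limitations.

## 1. Ionic membrane model

The membrane kinetics are the ten Tusscher–Noble–Noble–Panfilov (TNNP
2004) human ventricular myocyte model with mid-myocardial (M-cell)
parameters: twelve membrane currents (`i_na`, `i_k1`, `i_to`, `i_kr`,
`i_ks`, `i_cal`, `i_naca`, `i_nak`, `i_pca`, `i_pk`, `i_bna`, `i_bca`),
twelve Hodgkin–Huxley gates, and dynamic intracellular/SR calcium,
sodium and potassium with rapid-equilibrium calcium buffering. The
membrane voltage obeys

$$\frac{dV_m}{dt} = -\,I_\mathrm{ion} + I_\mathrm{stim},$$

with currents in pA/pF. `compute_ionic_currents()` exposes every
component plus the total, and `euler_step()` advances the 17-component
state by one time step.

### Integration scheme

Voltage and concentrations are advanced with forward Euler at
`dt = 0.02` ms. The gating variables use the Rush–Larsen exponential
update,

$$g \leftarrow g_\infty - (g_\infty - g)\,e^{-\Delta t/\tau_g},$$

because the fastest gate time constant ($\tau_m \approx 10^{-3}$ ms near
rest) makes a plain forward-Euler gate update unconditionally unstable
at any practical step size. Rush–Larsen is exact for frozen voltage,
unconditionally keeps gates inside their invariant interval, and is the
scheme used by the original published TNNP code. Two non-standard gate
rules are preserved from that formulation:

* the calcium-dependent inactivation gate `fca` and the SR release gate
  `g` are *not* updated when the update would increase them while
  $V_m > -60$ mV (inactivation latching during the plateau);
* the steady state of `fca` exceeds one at low calcium (its maximum is
  $1.53/1.46$), so its invariant interval is $[0, 1.53/1.46]$, not
  $[0, 1]$.

A state component leaving its invariant region (or going non-finite)
raises an error naming the offending time and suggesting a smaller
`dt`. Halving `dt` changes the action potential duration (APD) by less
than 1 ms (see the test suite).

## 2. Stretch-activated channel

The SAC carries a linear current–voltage relation gated sigmoidally by
the stretch ratio $\lambda$ (half-sarcomere length over its resting
value $0.97\ \mu$m):

$$I_\mathrm{SAC} = \frac{G_\mathrm{SAC}\,(V_m - V_\mathrm{rev})}
{1 + K e^{-\alpha(\lambda - 1)}},$$

with defaults $G_\mathrm{SAC} = 0.025$ nS/pF, $V_\mathrm{rev} = -20$ mV,
$K = 1$, $\alpha = 3$. At rest length the effective conductance is
$G_\mathrm{SAC}/2$; it rises monotonically with stretch and saturates at
$G_\mathrm{SAC}$. Example: at $V_m = -80$ mV, $\lambda = 1$,
$I_\mathrm{SAC} = -0.75$ pA/pF.

## 3. Myofilament model

Contraction uses a Negroni–Lascano-style cross-bridge scheme: three
troponin-system states (calcium-bound, attached cross-bridge, detached
power-stroke) exchange with free sites through four reversible reactions
whose rates depend on the half-sarcomere length, with normalized force

$$F = a_f\,h_c\,(X_2 + X_3)\,\phi(L),$$

where $\phi$ is a piecewise-linear overlap function of half-sarcomere
length. `twitch_from_calcium()` drives the sarcomere with any calcium
transient; `nl_steady_state()` gives the clamped-calcium algebraic fixed
point, which the integrator reproduces to machine precision.

## 4. Ventricle geometry, propagation and haemodynamics

The cavity is a prolate-spheroid-like single-layer wall discretized into
20 latitudinal fiber rings of 24 elements (480 membrane elements). Each
ring is a closed circumferential fiber; rings are electrically coupled
to their meridional neighbours with no-flux boundaries at the apex and
base. Propagation is isotropic monodomain, integrated with an explicit
finite-difference Laplacian whose per-edge coupling rate $D/\Delta x^2$
is capped near the apex (where element spacing shrinks) to stay inside
the explicit stability bound; violating the bound raises an error that
reports the admissible step.

Mechanics: ring wall tension is an active term (`k_active` times the
ring-mean myofilament force) plus an exponential passive term; the
thin-wall hoop relation converts tension to cavity pressure; flow
through a resistive aortic valve into a two-element Windkessel (and a
normally-closed resistive filling port) updates the cavity volume. The
new volume rescales every ring circumference by $\sqrt{V/V_0}$, setting
the half-sarcomere lengths and stretch ratios that the next
electrophysiology step sees — the mechano-electric loop closes with a
one-step lag. A small constant-volume redistribution term (`kappa`) lets
early-activated rings shorten against still-quiescent ones.

Preload is applied as an initial uniform stretch (0–25 % of reference
length, i.e. $\lambda$ = 1.00–1.25) before the 6 ms apical-cap
stimulus.

## Calibration (performed once, then frozen)

The tissue level has two free constants with no first-principles value
at this discretization:

* **Diffusion coefficient** `d_coeff = 1.4` mm²/ms, fixed so that the
  apex-to-base activation span is in the physiological several-tens-of-
  milliseconds range for this 20-ring geometry.
* **Tissue stimulus amplitude** `7.704` pA/pF, bisected by
  `calibrate_tissue_stimulus()` until the stimulated apex element
  crosses −60 mV at 4.4 ms at resting length.

Both values were calibrated once against those two targets only and are
frozen as package defaults; no other quantity was tuned. The active
tension scale `k_active = 15000` was likewise sized once to give a
physiological ejection fraction (≈0.40) and peak pressure (≈110 mmHg)
at zero preload, before any APD-related measurement.

The heart-failure arm rescales exactly six parameters
(`g_to`, `g_ks`, `g_k1`, `g_na`, `g_cal`, `k_naca`) by the factors in
`hf_modifiers()`. These factors are a transcription from an external
remodeling dataset, shipped in the default configuration file as a
calibration artifact: editing them invalidates every heart-failure
acceptance number.

## Marker definitions

Activation time (AT) is the first upward crossing of −60 mV after
stimulus onset; recovery time (RT) is the first downward crossing after
the post-activation peak; APD = RT − AT (≈80 % repolarization for this
model). All crossings are linearly interpolated, so markers are exact
for piecewise-linear fixtures (`synthetic_ap_trace()`). A fiber that
activates but shows no downward crossing is flagged as a
repolarization failure.

## Limitations and known discrepancies

* **SAC strength vs. published MEF magnitudes.** With the fixed SAC
  parameters, the effective resting conductance is 0.0125 nS/pF, which
  elevates the resting potential of the stretched M cell by only ~1–2 mV
  and moves the repolarization crossover to about −79 mV. Reproducing a
  ~10 mV resting elevation would need an effective conductance of
  ≈0.03 nS/pF — *above* the channel's saturating value of 0.025 — and
  stretch-induced repolarization failure at $\lambda = 1.3$ needs
  ≈0.05. No choice of the sigmoid shape parameters $(K, \alpha)$ can
  reach these at fixed $G_\mathrm{SAC} = 0.025$. The package keeps the
  fixed formulation and reports what it actually produces; the
  corresponding acceptance checks fail honestly rather than being
  tuned.
* **Heart-failure APD direction.** With the shipped remodeling factors
  the heart-failure cell has a slightly *shorter* APD than control: the
  APD-shortening effect of the reduced L-type calcium current
  (`f_cal = 0.85`) and enhanced Na/Ca exchange (`f_naca = 1.65`)
  outweighs the prolongation from the reduced potassium currents. The
  factors are a one-time transcription and are deliberately not
  re-derived to force APD prolongation; treat heart-failure comparisons
  as conditional on these values.
* The wall is a single layer: no transmural heterogeneity of cell type
  or stretch.
* Propagation is isotropic; fiber-direction anisotropy is out of scope.
* Stretch feeds back only through the SAC; mechanical modulation of
  calcium–troponin affinity is not modeled.
* Haemodynamics are lumped (two-element Windkessel, constant filling
  pressure): single-beat, fixed-preload protocols only.

## Reproducing the standard protocols

```{r protocols}
library(cardiomef)

# Fig.-3-shaped single-cell stretch study
sc <- run_single_cell_stretch(lambdas = c(1.0, 1.1, 1.2, 1.25, 1.3))
sc$markers

# Table-2-shaped preload comparison (control vs heart failure)
tab <- run_ventricle_preload(preloads = c(0, 10, 15, 20, 25))
tab

# Paired control / heart-failure PV loops
cmp <- run_hf_comparison(preload = 10)
cmp$haemodynamics
```

Everything is deterministic: identical configurations produce
bit-identical outputs, and every CSV written by the protocol functions
carries a provenance header with the package version and the settings
used.
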