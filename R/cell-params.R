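#' Default electrophysiological state of a resting myocyte
#'
#' Returns the canonical initial condition of the human ventricular myocyte
#' model (mid-myocardial variant): membrane voltage, the twelve gating
#' variables, and the intracellular/sarcoplasmic-reticulum ion
#' concentrations.  Gates are dimensionless in \eqn{[0, 1]}, concentrations
#' in mM, voltage in mV.
#'
#' @param vm Resting membrane voltage (mV).
#' @return A named numeric vector of length 17 with class `cardio_cell_state`.
#' @examples
#' st <- cell_state()
#' st[["vm"]]
#' @export
cell_state <- function(vm = -86.2) {
  st <- c(
    vm = vm, m = 0, h = 0.75, j = 0.75, xr1 = 0, xr2 = 1, xs = 0,
    r = 0, s = 1, d = 0, f = 1, fca = 1, g = 1,
    cai = 0.0002, ca_sr = 0.2, nai = 11.6, ki = 138.3
  )
  class(st) <- c("cardio_cell_state", "numeric")
  st
}

.state_names <- c(
  "vm", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "fca", "g",
  "cai", "ca_sr", "nai", "ki"
)

.gate_names <- .state_names[2:13]

validate_cell_state <- function(state) {
  if (length(state) != 17L) {
    abort("a cell state must have 17 entries (voltage, 12 gates, 4 concentrations)")
  }
  state <- as.numeric(state)
  bad <- which(!is.finite(state))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid cell state: non-finite value in '%s'",
      paste(.state_names[bad], collapse = "', '")
    ))
  }
  names(state) <- .state_names
  state
}

#' Membrane model parameters (mid-myocardial cell)
#'
#' Maximal conductances (nS/pF), the L-type channel permeability scale, and
#' pump/exchanger scale factors of the twelve-current human ventricular
#' membrane model, with the published mid-myocardial ("M cell") defaults.
#' `cm` is the capacitance constant entering the current-to-flux conversion
#' for the intracellular ion balances.
#'
#' @param g_na,g_k1,g_to,g_kr,g_ks,g_cal,g_bna,g_bca,g_pk,g_pca Maximal
#'   conductances / permeability scales of the respective currents.
#' @param k_nak Na+/K+ pump scale (pA/pF).
#' @param k_naca Na+/Ca2+ exchanger scale (pA/pF).
#' @param cm Membrane capacitance constant (uF).
#' @param cell_type Fixed to `"M"`; only the mid-myocardial parameter set is
#'   provided.
#' @return A list with class `cardio_cell_params`.
#' @examples
#' p <- cell_params()
#' p$g_ks
#' @export
cell_params <- function(g_na = 14.838, g_k1 = 5.405, g_to = 0.294,
                        g_kr = 0.096, g_ks = 0.062, g_cal = 0.000175,
                        g_bna = 0.00029, g_bca = 0.000592, g_pk = 0.0146,
                        g_pca = 0.825, k_nak = 1.362, k_naca = 1000,
                        cm = 0.185, cell_type = "M") {
  cell_type <- match.arg(cell_type, "M")
  p <- list(
    g_na = g_na, g_k1 = g_k1, g_to = g_to, g_kr = g_kr, g_ks = g_ks,
    g_cal = g_cal, g_bna = g_bna, g_bca = g_bca, g_pk = g_pk, g_pca = g_pca,
    k_nak = k_nak, k_naca = k_naca, cm = cm, cell_type = cell_type
  )
  num <- unlist(p[1:13])
  if (any(!is.finite(num)) || any(num < 0)) {
    abort("all conductances and scale factors must be finite and non-negative")
  }
  structure(p, class = "cardio_cell_params")
}

# fixed ordering expected by the compiled core
as_par_vector <- function(params) {
  stopifnot(inherits(params, "cardio_cell_params"))
  with(params, c(g_na, g_k1, g_to, g_kr, g_ks, g_cal, g_bna, g_bca,
                 g_pk, g_pca, k_nak, k_naca, cm))
}

#' Heart-failure remodeling factors
#'
#' Multiplicative scale factors applied to the maximal conductances of the
#' six currents remodeled in heart failure: the transient outward current,
#' the slow delayed rectifier, the inward rectifier, the fast sodium
#' current, the L-type calcium current, and the Na+/Ca2+ exchanger.
#' Potassium and sodium conductances are reduced and the exchanger is
#' up-regulated, which together prolong the action potential and depress
#' the calcium transient.
#'
#' The numeric defaults are a calibration artifact of this package,
#' transcribed from the heart-failure remodeling literature for human
#' ventricular models; edit them via the arguments or the configuration
#' file to explore other remodeling hypotheses.
#'
#' @param f_to,f_ks,f_k1,f_na,f_cal,f_naca Positive multiplicative factors.
#' @return A list with class `cardio_hf_modifiers`.
#' @examples
#' identity_mods <- hf_modifiers(1, 1, 1, 1, 1, 1)
#' @export
hf_modifiers <- function(f_to = 0.36, f_ks = 0.5, f_k1 = 0.75,
                         f_na = 0.60, f_cal = 0.85, f_naca = 1.65) {
  m <- list(f_to = f_to, f_ks = f_ks, f_k1 = f_k1, f_na = f_na,
            f_cal = f_cal, f_naca = f_naca)
  v <- unlist(m)
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("heart-failure factors must be finite and strictly positive")
  }
  structure(m, class = "cardio_hf_modifiers")
}

#' Apply heart-failure remodeling to a parameter set
#'
#' Multiplies exactly the six remodeled conductance/exchanger scales and
#' leaves every other parameter untouched.  Identity factors return a
#' parameter set identical to the input.
#'
#' @param params A [cell_params()] object.
#' @param mods A [hf_modifiers()] object.
#' @return A new `cardio_cell_params` object.
#' @examples
#' hf <- apply_hf(cell_params(), hf_modifiers())
#' hf$g_to / cell_params()$g_to
#' @export
apply_hf <- function(params, mods = hf_modifiers()) {
  stopifnot(inherits(params, "cardio_cell_params"))
  if (!inherits(mods, "cardio_hf_modifiers")) {
    abort("`mods` must be created with hf_modifiers()")
  }
  out <- params
  out$g_to <- params$g_to * mods$f_to
  out$g_ks <- params$g_ks * mods$f_ks
  out$g_k1 <- params$g_k1 * mods$f_k1
  out$g_na <- params$g_na * mods$f_na
  out$g_cal <- params$g_cal * mods$f_cal
  out$k_naca <- params$k_naca * mods$f_naca
  out
}

#' Stimulus specification
#'
#' Rectangular current pulse; positive amplitude depolarizes.  The default
#' is the single-cell protocol: 52 pA/pF for 1 ms starting at t = 0.
#'
#' @param amplitude Current density (pA/pF).
#' @param onset Pulse onset (ms).
#' @param duration Pulse width (ms); must be positive.
#' @param period Pacing period (ms), or `NA` for a single pulse.
#' @return A list with class `cardio_stimulus`.
#' @examples
#' stimulus_spec()                       # single-cell pulse
#' stimulus_spec(period = 1000)          # 1 Hz pacing
#' @export
stimulus_spec <- function(amplitude = 52, onset = 0, duration = 1,
                          period = NA_real_) {
  if (!is.finite(duration) || duration <= 0) abort("stimulus duration must be positive")
  if (!is.na(period) && period <= duration) abort("stimulus period must exceed its duration")
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 period = period),
            class = "cardio_stimulus")
}

as_stim_vector <- function(stim) {
  stopifnot(inherits(stim, "cardio_stimulus"))
  c(stim$amplitude, stim$onset, stim$duration,
    if (is.na(stim$period)) -1 else stim$period)
}
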