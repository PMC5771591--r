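#' Stretch-activated channel parameters
#'
#' The stretch-activated channel (SAC) carries a current linear in the
#' driving force and gated sigmoidally by the stretch ratio:
#' \deqn{I_{SAC} = G_{SAC} \frac{V_m - V_{rev}}{1 + K e^{-\alpha(\lambda - 1)}}}
#' Units: `g_sac` is in nS/pF, so multiplying by a voltage in mV yields a
#' current density in pA/pF, the same normalization as the membrane model
#' currents.  Note that at resting length (\eqn{\lambda = 1}) with `k = 1`
#' the effective conductance is exactly `g_sac / 2` -- the channel is not
#' silent at rest.
#'
#' @param g_sac Maximum conductance (nS/pF); set 0 to disable the channel.
#' @param v_rev Reversal potential (mV).
#' @param k Zero-stretch current parameter (dimensionless).
#' @param alpha Stretch sensitivity (dimensionless).
#' @param half_sl0 Resting half-sarcomere length (um).
#' @return A list with class `cardio_sac_params`.
#' @examples
#' sac_params()
#' compute_isac(-80, 1.2, sac_params())
#' @export
sac_params <- function(g_sac = 0.025, v_rev = -20, k = 1, alpha = 3,
                       half_sl0 = 0.97) {
  if (!is.finite(g_sac) || g_sac < 0) abort("g_sac must be >= 0")
  if (!is.finite(k) || k < 0) abort("k must be >= 0")
  if (!is.finite(half_sl0) || half_sl0 <= 0) abort("half_sl0 must be positive")
  if (!is.finite(alpha)) abort("alpha must be finite")
  structure(list(g_sac = g_sac, v_rev = v_rev, k = k, alpha = alpha,
                 half_sl0 = half_sl0),
            class = "cardio_sac_params")
}

#' Disabled stretch-activated channel
#'
#' Convenience constructor equivalent to `sac_params(g_sac = 0)`.
#' @return A `cardio_sac_params` object with zero conductance.
#' @export
sac_disabled <- function() sac_params(g_sac = 0)

as_sac_vector <- function(sac) {
  if (is.null(sac)) return(numeric(0))
  stopifnot(inherits(sac, "cardio_sac_params"))
  c(sac$g_sac, sac$v_rev, sac$k, sac$alpha)
}

#' Stretch ratio from half-sarcomere lengths
#'
#' \eqn{\lambda = HalfSL / HalfSL_0}.  No clamping is applied: compression
#' (\eqn{\lambda < 1}) simply reduces the stretch-activated current.
#'
#' @param half_sl Current half-sarcomere length (um); vectorized.
#' @param half_sl0 Resting half-sarcomere length (um), default 0.97.
#' @return Dimensionless stretch ratio(s).
#' @examples
#' stretch_ratio(1.164)   # 1.2
#' @export
stretch_ratio <- function(half_sl, half_sl0 = 0.97) {
  if (any(!is.finite(half_sl)) || any(half_sl <= 0)) {
    abort("half-sarcomere lengths must be finite and positive")
  }
  if (!is.finite(half_sl0) || half_sl0 <= 0) {
    abort("the resting half-sarcomere length must be positive")
  }
  half_sl / half_sl0
}

#' Stretch-activated channel current
#'
#' Evaluates the SAC current density for membrane voltage(s) `vm` and
#' stretch ratio(s) `lambda`.  The current is inward (negative,
#' depolarizing) whenever `vm` is below the reversal potential.
#'
#' @param vm Membrane voltage (mV); vectorized.
#' @param lambda Stretch ratio (dimensionless); vectorized.
#' @param params A [sac_params()] object.
#' @return Current density (pA/pF).
#' @examples
#' compute_isac(-80, 1.0)  # -0.75 pA/pF with the default parameters
#' @export
compute_isac <- function(vm, lambda, params = sac_params()) {
  stopifnot(inherits(params, "cardio_sac_params"))
  if (any(!is.finite(vm)) || any(!is.finite(lambda))) {
    abort("vm and lambda must be finite")
  }
  params$g_sac * (vm - params$v_rev) /
    (1 + params$k * exp(-params$alpha * (lambda - 1)))
}

#' Effective stretch-dependent conductance
#'
#' The voltage-independent factor
#' \eqn{G_{SAC} / (1 + K e^{-\alpha(\lambda-1)})}; strictly increasing in
#' the stretch ratio for positive `k` and `alpha`, saturating at `g_sac`.
#'
#' @inheritParams compute_isac
#' @return Conductance (nS/pF).
#' @export
sac_conductance <- function(lambda, params = sac_params()) {
  stopifnot(inherits(params, "cardio_sac_params"))
  params$g_sac / (1 + params$k * exp(-params$alpha * (lambda - 1)))
}
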