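#' Membrane ionic currents at a given state
#'
#' Evaluates the twelve membrane-model currents, adds the externally
#' supplied stretch-activated current, and returns their arithmetic total.
#' The total equals the component sum to machine precision by construction.
#'
#' @param state A [cell_state()] vector.
#' @param params A [cell_params()] object.
#' @param i_sac Stretch-activated current density (pA/pF); 0 when the
#'   channel is disabled.
#' @return A one-row tibble with one column per current (`i_na`, `i_nak`,
#'   `i_bna`, `i_k1`, `i_to`, `i_kr`, `i_ks`, `i_pk`, `i_cal`, `i_naca`,
#'   `i_pca`, `i_bca`, `i_sac`) and the total `i_total`, all in pA/pF.
#' @examples
#' compute_ionic_currents(cell_state(), cell_params())
#' @export
compute_ionic_currents <- function(state, params = cell_params(), i_sac = 0) {
  state <- validate_cell_state(state)
  if (!is.finite(i_sac)) abort("i_sac must be finite")
  cur <- cpp_cell_currents(state, as_par_vector(params), i_sac)
  as_tibble(as.list(cur))
}

#' Advance a myocyte one forward-Euler step
#'
#' Advances the membrane voltage by \eqn{\Delta V_m = -\Delta t (I_{ion} -
#' I_{stim})} (currents in pA/pF, so a positive stimulus depolarizes) and
#' the gates and concentrations by the model rate equations.  Gating
#' variables are clipped into \eqn{[0, 1]} only for overshoots below 1e-9;
#' larger overshoots raise an error, as does any non-finite state.
#'
#' @inheritParams compute_ionic_currents
#' @param istim Stimulus current density (pA/pF).
#' @param dt Time step (ms); the model default is 0.02 ms.
#' @param iion_override If supplied, the total ionic current is replaced by
#'   this fixed value for the voltage update (diagnostic use only; the
#'   gates and concentrations still follow the model equations).
#' @return The updated state vector.
#' @examples
#' st <- euler_step(cell_state(), istim = 52)
#' @export
euler_step <- function(state, params = cell_params(), istim = 0, i_sac = 0,
                       dt = 0.02, iion_override = NULL) {
  state <- validate_cell_state(state)
  if (!is.finite(dt) || dt <= 0) abort("dt must be positive")
  if (!is.null(iion_override)) {
    # diagnostic path: voltage update with the prescribed total current
    res <- cpp_cell_step(state, as_par_vector(params), istim, i_sac, dt)
    st <- res$state
    st[1] <- state[[1]] - dt * (iion_override - istim)
    names(st) <- .state_names
    return(structure(st, class = c("cardio_cell_state", "numeric")))
  }
  res <- cpp_cell_step(state, as_par_vector(params), istim, i_sac, dt)
  if (res$status == 1L) {
    abort(sprintf("numerical instability (non-finite state) at dt = %g ms", dt))
  }
  if (res$status == 2L) {
    abort(sprintf("gating variable overshot [0, 1] beyond tolerance at dt = %g ms", dt))
  }
  st <- res$state
  names(st) <- .state_names
  structure(st, class = c("cardio_cell_state", "numeric"))
}

#' Relax a myocyte to its quiescent resting state
#'
#' Integrates the unstimulated cell for `duration` ms at fixed stretch,
#' optionally with periodic pacing (pass a `stim`), and returns the final
#' state.  Ten or more seconds of quiescence drive the model to a stable
#' resting point.
#'
#' @inheritParams run_paced_cell
#' @param duration Equilibration time (ms).
#' @param init Starting state; defaults to [cell_state()].
#' @return The equilibrated state vector.
#' @export
equilibrate_cell <- function(params = cell_params(), sac = NULL, lambda = 1,
                             duration = 10000, dt = 0.02, stim = NULL,
                             init = NULL) {
  init <- validate_cell_state(init %||% cell_state())
  sv <- if (is.null(stim)) c(0, 0, 0, -1) else as_stim_vector(stim)
  st <- cpp_equilibrate_cell(init, as_par_vector(params), as_sac_vector(sac),
                             lambda, sv, duration, dt)
  names(st) <- .state_names
  structure(st, class = c("cardio_cell_state", "numeric"))
}

#' Simulate a paced myocyte under steady stretch
#'
#' Runs the single-cell protocol: the cell is pre-paced to approach its
#' steady state (by default 10 beats at 1 Hz at the same stretch), then a
#' recorded run of `duration` ms is performed with the given stimulus.
#' The stretch ratio is held fixed for the whole run (steady stretch), and
#' the stretch-activated current is evaluated at that ratio each step.
#'
#' @param params A [cell_params()] object (pass an [apply_hf()] result for
#'   heart failure).
#' @param stim A [stimulus_spec()]; default 52 pA/pF for 1 ms at t = 0.
#' @param sac A [sac_params()] object, or `NULL` to disable the channel.
#' @param lambda Steady stretch ratio (dimensionless, >= 0).
#' @param duration Recorded duration (ms).
#' @param dt Time step (ms).
#' @param stride Output sampling interval (ms).
#' @param prepace Number of 1 Hz conditioning beats before recording; 0
#'   starts from `init` directly.
#' @param init Starting state before conditioning; defaults to [cell_state()].
#' @param full_states Record all 17 state variables (not just `vm`, `cai`).
#' @return A tibble with columns `time` (ms), `vm` (mV), `cai` (mM), and,
#'   if requested, one column per state variable; carries the run settings
#'   in attributes and class `cardio_trace`.
#' @examples
#' \donttest{
#' tr <- run_paced_cell(lambda = 1.2, sac = sac_params(), duration = 500,
#'                      prepace = 2)
#' }
#' @export
run_paced_cell <- function(params = cell_params(), stim = stimulus_spec(),
                           sac = NULL, lambda = 1, duration = 1000,
                           dt = 0.02, stride = 0.5, prepace = 10,
                           init = NULL, full_states = FALSE) {
  if (!is.finite(lambda) || lambda < 0) abort("lambda must be >= 0")
  st <- validate_cell_state(init %||% cell_state())
  pv <- as_par_vector(params)
  sv <- as_sac_vector(sac)
  if (prepace > 0) {
    pace <- c(stim$amplitude, 0, stim$duration, 1000)
    st <- cpp_equilibrate_cell(st, pv, sv, lambda, pace, prepace * 1000, dt)
  }
  res <- cpp_run_cell(st, pv, sv, lambda, as_stim_vector(stim), duration,
                      dt, stride, full_states)
  out <- tibble(time = res$time, vm = res$vm, cai = res$cai)
  if (full_states) {
    sm <- res$states
    colnames(sm) <- .state_names
    out <- dplyr::bind_cols(out, as_tibble(sm[, setdiff(.state_names, c("vm", "cai")),
                                              drop = FALSE]))
  }
  fs <- res$final_state
  names(fs) <- .state_names
  structure(out,
            class = c("cardio_trace", class(out)),
            lambda = lambda, dt = dt, stim = stim,
            sac = sac %||% sac_disabled(), params = params,
            final_state = fs)
}
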