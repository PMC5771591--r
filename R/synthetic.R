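#' Synthetic action-potential trace with known markers
#'
#' Fixture generator for marker-extraction testing: a stylized action
#' potential built from piecewise-linear segments so that the -60 mV
#' upstroke and repolarization crossings fall exactly at the prescribed
#' activation and recovery times.  The shape is resting potential up to
#' the upstroke foot, a fast linear upstroke through the threshold at
#' `at`, a peak, a slowly declining plateau, and a linear late
#' repolarization through the threshold at `rt`, returning to rest.
#'
#' @param at Ground-truth activation time (ms).
#' @param rt Ground-truth recovery time (ms); `NA` produces a
#'   non-repolarizing trace that stays at the plateau.
#' @param duration Trace length (ms).
#' @param dt Sampling interval (ms).
#' @param v_rest Resting potential (mV).
#' @param v_peak Peak potential (mV).
#' @param v_plateau Plateau potential at the start of late repolarization
#'   (mV).
#' @param threshold Marker threshold the crossings are anchored to (mV).
#' @param upstroke_vel Upstroke slope (mV/ms).
#' @param repol_vel Late repolarization slope (mV/ms, positive number).
#' @return A tibble `time`, `vm` with the ground truth in attributes `at`,
#'   `rt`.
#' @examples
#' tr <- synthetic_ap_trace(at = 5, rt = 305)
#' detect_at(tr)
#' @export
synthetic_ap_trace <- function(at = 5, rt = 305, duration = NULL, dt = 0.5,
                               v_rest = -85, v_peak = 38, v_plateau = 0,
                               threshold = -60, upstroke_vel = 200,
                               repol_vel = 1.5) {
  if (at <= 0) abort("`at` must be positive")
  if (!is.na(rt) && rt <= at) abort("`rt` must exceed `at`")
  duration <- duration %||% (if (is.na(rt)) at + 500 else rt + 100)
  time <- seq(0, duration, by = dt)

  # upstroke anchored so vm(at) == threshold
  t_foot <- at - (threshold - v_rest) / upstroke_vel
  t_top <- at + (v_peak - threshold) / upstroke_vel
  if (t_foot <= 0) abort("`at` too early for the requested upstroke velocity")

  if (is.na(rt)) {
    xs <- c(0, t_foot, t_top, duration)
    ys <- c(v_rest, v_rest, v_peak, v_plateau)
  } else {
    # late repolarization anchored so vm(rt) == threshold
    t_rep0 <- rt - (v_plateau - threshold) / repol_vel
    t_rep1 <- rt + (threshold - v_rest) / repol_vel
    if (t_rep0 <= t_top) abort("`rt` too close to `at` for the plateau shape")
    xs <- c(0, t_foot, t_top, t_rep0, t_rep1, duration)
    ys <- c(v_rest, v_rest, v_peak, v_plateau, v_rest, v_rest)
  }
  vm <- approx(xs, ys, xout = pmin(time, max(xs)), rule = 2)$y
  structure(tibble(time = time, vm = vm),
            class = c("cardio_trace", class(tibble())),
            at = at, rt = rt, threshold = threshold)
}

#' Synthetic calcium transient
#'
#' Stylized intracellular calcium transient (diastolic baseline plus a
#' log-normal-shaped bump) for driving the myofilament model without
#' running the cell model.
#'
#' @param duration Trace length (ms).
#' @param dt Sampling interval (ms).
#' @param diastolic Baseline calcium (mM).
#' @param amplitude Peak amplitude above baseline (mM).
#' @param t_peak Time of the peak (ms).
#' @param width Log-scale width of the bump.
#' @return A tibble `time`, `cai`.
#' @export
synthetic_cai_trace <- function(duration = 1000, dt = 1,
                                diastolic = 0.0002, amplitude = 0.0008,
                                t_peak = 35, width = 0.9) {
  time <- seq(0, duration, by = dt)
  bump <- ifelse(time > 0,
                 exp(-(log(pmax(time, 1e-9) / t_peak))^2 / (2 * width^2)),
                 0)
  tibble(time = time, cai = diastolic + amplitude * bump)
}
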