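#' Myofilament (crossbridge/Ca-kinetics) model parameters
#'
#' Four-state Negroni-Lascano style myofilament model.  Troponin systems
#' cycle through free sites (`TS`), calcium-bound detached sites
#' (`TSCa3`), calcium-bound attached crossbridges (`TSCa3*`), and
#' calcium-free attached crossbridges (`TS*`); attached crossbridges act as
#' linear springs whose anchor slides toward a preferred elongation `hc`.
#' Developed force is
#' \deqn{F = A\, (L - X)\, ([TSCa_3^*] + [TS^*])\, w(L)}
#' with \eqn{w(L)} the filament-overlap factor, rising linearly between
#' `l_a` and `l_opt`.  Force is reported in normalized model units (the
#' scale `a_f` is the single documented calibration constant; the ventricle
#' model consumes normalized force and applies its own wall scaling).
#'
#' Rates are in 1/ms; calcium binding is cooperative (third power of the
#' micromolar calcium concentration).
#'
#' @param tt Total troponin-system concentration (uM).
#' @param y1 Ca binding rate constant (1/(uM^3 ms)).
#' @param z1 Ca unbinding rate from detached sites (1/ms).
#' @param y2 Crossbridge attachment rate (1/ms).
#' @param z2 Crossbridge detachment rate to the Ca-bound detached state (1/ms).
#' @param y3 Ca release rate from attached crossbridges (1/ms).
#' @param z3 Ca rebinding rate to attached crossbridges (1/(uM^3 ms)).
#' @param y4 Detachment rate of Ca-free crossbridges (1/ms).
#' @param b Crossbridge anchor sliding rate (1/ms).
#' @param hc Preferred crossbridge elongation (um).
#' @param a_f Force scale (normalized-force units per uM um).
#' @param l_a,l_opt Overlap-function foot and optimum (um, half-sarcomere).
#' @param k_p,beta_p Passive exponential stiffness (normalized units) and
#'   steepness (1/um); zero passive force by default, the tissue model
#'   carries its own wall-level passive stress.
#' @param l0 Resting half-sarcomere length (um).
#' @return A list with class `cardio_sarc_params`.
#' @export
sarcomere_params <- function(tt = 70, y1 = 0.039, z1 = 0.03, y2 = 0.0087,
                             z2 = 0.0052, y3 = 0.012, z3 = 0.0039,
                             y4 = 0.027, b = 1.2, hc = 0.005, a_f = 9.5,
                             l_a = 0.55, l_opt = 1.05, k_p = 0, beta_p = 10,
                             l0 = 0.97) {
  p <- list(tt = tt, y1 = y1, z1 = z1, y2 = y2, z2 = z2, y3 = y3, z3 = z3,
            y4 = y4, b = b, hc = hc, a_f = a_f, l_a = l_a, l_opt = l_opt,
            k_p = k_p, beta_p = beta_p, l0 = l0)
  v <- unlist(p)
  if (any(!is.finite(v))) abort("sarcomere parameters must be finite")
  if (tt <= 0 || l0 <= 0 || l_opt <= l_a) {
    abort("need tt > 0, l0 > 0 and l_opt > l_a")
  }
  structure(p, class = "cardio_sarc_params")
}

as_nl_par_vector <- function(p) {
  stopifnot(inherits(p, "cardio_sarc_params"))
  with(p, c(tt, y1, z1, y2, z2, y3, z3, y4, b, hc, a_f, l_a, l_opt,
            k_p, beta_p, l0))
}

#' Resting myofilament state
#'
#' All troponin systems free, the crossbridge anchor relaxed at its
#' preferred elongation, half-sarcomere length at `half_sl`.
#'
#' @param half_sl Initial half-sarcomere length (um).
#' @param params A [sarcomere_params()] object.
#' @return Named numeric vector `(half_sl, x, tsca3, tsca3s, tss)` with
#'   class `cardio_sarc_state`.
#' @export
sarcomere_state <- function(half_sl = 0.97, params = sarcomere_params()) {
  if (!is.finite(half_sl) || half_sl <= 0) abort("half_sl must be positive")
  st <- c(half_sl = half_sl, x = half_sl - params$hc,
          tsca3 = 0, tsca3s = 0, tss = 0)
  class(st) <- c("cardio_sarc_state", "numeric")
  st
}

.nl_state_names <- c("half_sl", "x", "tsca3", "tsca3s", "tss")

#' Advance the myofilament model one step
#'
#' @param state A [sarcomere_state()] vector.
#' @param cai Intracellular calcium (mM), as produced by the cell model.
#' @param params A [sarcomere_params()] object.
#' @param dt Time step (ms).
#' @param mode `"isometric"` (length held), `"isotonic"` (length evolves
#'   against `load`), or `"prescribed"` (length set to `half_sl`).
#' @param half_sl Target length for `"prescribed"` mode (um).
#' @param load External load for `"isotonic"` mode (normalized force units).
#' @return The updated state, with attributes `force` (active developed
#'   force, normalized units) and `passive_force`.
#' @export
nl_step <- function(state, cai, params = sarcomere_params(), dt = 0.02,
                    mode = c("isometric", "isotonic", "prescribed"),
                    half_sl = NULL, load = 0) {
  mode <- match.arg(mode)
  if (!is.finite(dt) || dt <= 0) abort("dt must be positive")
  if (!is.finite(cai) || cai < 0) abort("cai must be >= 0")
  imode <- match(mode, c("isometric", "isotonic", "prescribed")) - 1L
  aux <- switch(mode,
    isometric = 0,
    isotonic = load,
    prescribed = {
      if (is.null(half_sl)) abort("prescribed mode needs `half_sl`")
      half_sl
    }
  )
  res <- cpp_nl_step(as.numeric(state), cai, as_nl_par_vector(params), dt,
                     imode, aux)
  if (res$status != 0) {
    abort(sprintf(
      "myofilament step unstable (code %d); try a smaller dt than %g ms",
      res$status, dt))
  }
  st <- res$state
  names(st) <- .nl_state_names
  structure(st, class = c("cardio_sarc_state", "numeric"),
            force = res$force, passive_force = res$passive_force)
}

#' Force twitch from a calcium transient
#'
#' Drives the myofilament model with a uniformly sampled calcium trace and
#' returns the developed-force and half-sarcomere-length time series.
#'
#' @param cai_trace A data frame with columns `time` (ms) and `cai` (mM),
#'   uniformly sampled (a [run_paced_cell()] trace works directly).
#' @param params A [sarcomere_params()] object.
#' @param mode `"isometric"` or `"prescribed"`; prescribed mode requires a
#'   `half_sl` column in `cai_trace`.
#' @param half_sl Initial (isometric) half-sarcomere length (um).
#' @param substeps Integration substeps per calcium sample; the default
#'   keeps the internal step at or below 0.02 ms-scale accuracy for
#'   millisecond-sampled input.
#' @return A tibble `time`, `force`, `passive_force`, `half_sl` with class
#'   `cardio_twitch`.
#' @examples
#' ca <- tibble::tibble(time = seq(0, 600, 1),
#'                      cai = 2e-4 + 8e-4 * exp(-(time - 30)^2 / 2000) *
#'                            (time > 5))
#' tw <- twitch_from_calcium(ca)
#' @export
twitch_from_calcium <- function(cai_trace, params = sarcomere_params(),
                                mode = c("isometric", "prescribed"),
                                half_sl = params$l0, substeps = NULL) {
  mode <- match.arg(mode)
  if (!is.data.frame(cai_trace) || nrow(cai_trace) == 0) {
    abort("`cai_trace` must be a non-empty data frame with time and cai columns")
  }
  if (!all(c("time", "cai") %in% names(cai_trace))) {
    abort("`cai_trace` needs `time` and `cai` columns")
  }
  tt <- cai_trace$time
  if (nrow(cai_trace) < 2) abort("need at least two calcium samples")
  dts <- diff(tt)
  if (max(abs(dts - dts[1])) > 1e-6 * max(dts[1], 1)) {
    abort("`cai_trace` must be uniformly sampled")
  }
  dt_sample <- dts[1]
  substeps <- substeps %||% max(1L, ceiling(dt_sample / 0.1))
  imode <- if (mode == "isometric") 0L else 2L
  len <- if (imode == 2L) {
    if (!"half_sl" %in% names(cai_trace)) {
      abort("prescribed mode needs a `half_sl` column")
    }
    as.numeric(cai_trace$half_sl)
  } else numeric(0)
  st <- sarcomere_state(half_sl, params)
  res <- cpp_nl_run(as.numeric(st), as.numeric(cai_trace$cai),
                    as_nl_par_vector(params), dt_sample, imode, len,
                    as.integer(substeps))
  structure(
    tibble(time = tt, force = res$force, passive_force = res$passive_force,
           half_sl = res$half_sl),
    class = c("cardio_twitch", class(tibble())),
    params = params, mode = mode
  )
}

#' Steady-state myofilament activation at clamped calcium
#'
#' Closed-form fixed point of the troponin/crossbridge kinetics for a
#' constant calcium concentration and fixed length: the three-state linear
#' system is solved algebraically and the corresponding isometric force
#' returned.  Useful as an independent check on the time integrator.
#'
#' @param cai Clamped calcium (mM).
#' @param half_sl Half-sarcomere length (um).
#' @param params A [sarcomere_params()] object.
#' @return A list with the steady state fractions and `force`.
#' @export
nl_steady_state <- function(cai, half_sl = 0.97,
                            params = sarcomere_params()) {
  ca3 <- (cai * 1000)^3
  p <- params
  # unknowns: tsca3, tsca3s, tss; TS = tt - sum
  # 0 = y1 ca3 (tt - a - b - c) - (z1 + y2) a + z2 b
  # 0 = y2 a - (z2 + y3) b + z3 ca3 c
  # 0 = y3 b - (z3 ca3 + y4) c
  A <- rbind(
    c(-(p$y1 * ca3 + p$z1 + p$y2), -p$y1 * ca3 + p$z2, -p$y1 * ca3),
    c(p$y2, -(p$z2 + p$y3), p$z3 * ca3),
    c(0, p$y3, -(p$z3 * ca3 + p$y4))
  )
  rhs <- c(-p$y1 * ca3 * p$tt, 0, 0)
  sol <- solve(A, rhs)
  w <- pmin(pmax((half_sl - p$l_a) / (p$l_opt - p$l_a), 0), 1)
  force <- p$a_f * p$hc * (sol[2] + sol[3]) * w
  list(tsca3 = sol[1], tsca3s = sol[2], tss = sol[3],
       attached = sol[2] + sol[3], force = unname(force))
}
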