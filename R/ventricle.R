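#' Fiber-ring ventricle geometry
#'
#' The ventricular wall is a single layer of circumferential muscle fibers
#' arranged as a stack of circular rings approximating a truncated
#' (hemi-)ellipsoid of revolution: ring `i` sits at polar angle
#' \eqn{\theta_i} with unstressed radius \eqn{r_i = b \sin\theta_i} and
#' axial position \eqn{z_i = a(1 - \cos\theta_i)}, apex first.  The cavity
#' volume is the discrete solid of revolution of the ring radii; the outer
#' boundary length \eqn{L_V} is the equatorial-ring circumference.  Each
#' ring is a closed chain of half-sarcomeres in series, so its unstressed
#' circumference divided by the resting half-sarcomere length gives the
#' half-sarcomere count \eqn{N_i}, and \eqn{HalfSL_i = C_i / N_i} at any
#' deformation -- whence \eqn{\lambda_i = C_i / C_{i,0}}.
#'
#' Default dimensions give an unstressed cavity volume of roughly 100 mL,
#' i.e. an end-diastolic volume in the 120 mL class at 10 percent preload.
#'
#' @param n_rings Number of fiber rings stacked apex to base.
#' @param nodes_per_ring Electrical elements per ring.
#' @param base_radius Equatorial (base) inner radius `b` (mm).
#' @param apex_base_length Apex-to-base semi-axis `a` (mm).
#' @param half_sl0 Resting half-sarcomere length (um).
#' @return A list with class `cardio_geometry`: ring radii `r0` (mm), axial
#'   extents `dz` (mm), unstressed circumferences `circ0` (um),
#'   half-sarcomere counts `n_half_sl`, the boundary length `l_v0` (um),
#'   its count `n_total`, the unstressed cavity volume `v0` (mL), and the
#'   apex stimulus element index.
#' @examples
#' geo <- ventricle_geometry()
#' geo$v0
#' @export
ventricle_geometry <- function(n_rings = 20, nodes_per_ring = 24,
                               base_radius = 29.8, apex_base_length = 53.7,
                               half_sl0 = 0.97) {
  if (n_rings < 1 || nodes_per_ring < 3) {
    abort("need n_rings >= 1 and nodes_per_ring >= 3")
  }
  th_edge <- seq(0, pi / 2, length.out = n_rings + 1)
  th_mid <- (th_edge[-1] + th_edge[-(n_rings + 1)]) / 2
  r0 <- base_radius * sin(th_mid)                       # mm
  z_edge <- apex_base_length * (1 - cos(th_edge))       # mm
  dz <- diff(z_edge)
  z_mid <- apex_base_length * (1 - cos(th_mid))
  v0 <- sum(pi * r0^2 * dz) / 1000                      # mm^3 -> mL
  circ0 <- 2 * pi * r0 * 1000                           # um
  n_half_sl <- circ0 / half_sl0
  # meridian arc length between neighbouring ring centres (mm)
  arc <- sqrt(diff(base_radius * sin(th_mid))^2 + diff(z_mid)^2)
  structure(list(
    n_rings = n_rings, nodes_per_ring = nodes_per_ring,
    base_radius = base_radius, apex_base_length = apex_base_length,
    half_sl0 = half_sl0, theta = th_mid, r0 = r0, z = z_mid, dz = dz,
    circ0 = circ0, n_half_sl = n_half_sl,
    l_v0 = max(circ0), n_total = max(circ0) / half_sl0, v0 = v0,
    arc_axial = arc, apex_index = 1L
  ), class = "cardio_geometry")
}

#' Inter-element coupling coefficients
#'
#' Converts the isotropic diffusion coefficient `d_coeff` (mm^2/ms) into
#' explicit finite-difference coupling rates `D / dx^2` (1/ms) for the
#' within-ring and between-ring neighbour pairs, using each ring's element
#' spacing and the meridian arc between ring centres.  A cap keeps the
#' near-apex rings (tiny circumference, hence tiny spacing) inside the
#' explicit-update stability bound.
#'
#' @param geometry A [ventricle_geometry()] object.
#' @param d_coeff Diffusion coefficient (mm^2/ms).
#' @param cap Maximum per-edge coupling rate (1/ms).
#' @return List with `g_ring` (per ring) and `g_ax` (per interface), 1/ms.
#' @export
coupling_coefficients <- function(geometry, d_coeff, cap = 5) {
  stopifnot(inherits(geometry, "cardio_geometry"))
  if (!is.finite(d_coeff) || d_coeff < 0) abort("d_coeff must be >= 0")
  dx_ring <- (geometry$circ0 / 1000) / geometry$nodes_per_ring  # mm
  g_ring <- pmin(d_coeff / dx_ring^2, cap)
  g_ax <- if (geometry$n_rings > 1) {
    pmin(d_coeff / geometry$arc_axial^2, cap)
  } else {
    numeric(0)
  }
  list(g_ring = g_ring, g_ax = g_ax)
}

#' Explicit diffusion update of a voltage field
#'
#' One (or several) explicit finite-difference diffusion steps on the
#' ring-lattice: closed rings, no-flux boundaries at the apex and base
#' openings.  A uniform field, or zero diffusion, leaves the field
#' unchanged; on a single closed ring the node sum is conserved exactly.
#' Violating the explicit stability bound raises an error reporting the
#' admissible time step.
#'
#' @param vm_field Numeric matrix (`n_rings` x `nodes_per_ring`) or vector
#'   of length `n_rings * nodes_per_ring`, ring-major.
#' @param geometry A [ventricle_geometry()] object.
#' @param d_coeff Diffusion coefficient (mm^2/ms).
#' @param dt Time step (ms).
#' @param nsteps Number of consecutive steps.
#' @return The updated field, same shape as the input.
#' @export
diffusion_step <- function(vm_field, geometry, d_coeff, dt, nsteps = 1) {
  stopifnot(inherits(geometry, "cardio_geometry"))
  if (!is.finite(dt) || dt <= 0) abort("dt must be positive")
  g <- coupling_coefficients(geometry, d_coeff)
  tot <- 2 * g$g_ring
  if (geometry$n_rings > 1) {
    tot <- tot + c(g$g_ax, 0) + c(0, g$g_ax)
  }
  if (dt * max(tot) >= 1) {
    abort(sprintf(
      "explicit diffusion unstable: dt * max coupling = %.3f >= 1; use dt < %.5f ms",
      dt * max(tot), 1 / max(tot)))
  }
  was_matrix <- is.matrix(vm_field)
  v <- if (was_matrix) as.numeric(t(vm_field)) else as.numeric(vm_field)
  if (length(v) != geometry$n_rings * geometry$nodes_per_ring) {
    abort("field size does not match the geometry")
  }
  out <- cpp_diffuse(v, geometry$n_rings, geometry$nodes_per_ring,
                     g$g_ring, g$g_ax, dt, as.integer(nsteps))
  if (was_matrix) {
    matrix(out, nrow = geometry$n_rings, byrow = TRUE)
  } else {
    out
  }
}

#' Half-sarcomere length and stretch ratio from the cavity state
#'
#' Translates a cavity volume (or directly a boundary length) into the
#' per-ring half-sarcomere length and stretch ratio: the ring radii scale
#' with the square root of the volume ratio (radial deformation of the
#' single-layer wall), each circumference is divided by its unstressed
#' half-sarcomere count, and the stretch ratio is the length ratio to the
#' resting half-sarcomere length.
#'
#' @param geometry A [ventricle_geometry()] object.
#' @param volume Cavity volume (mL); mutually exclusive with `lv_length`.
#' @param lv_length Outer boundary (equatorial circumference) length (um).
#' @return A tibble with `ring`, `circumference` (um), `half_sl` (um) and
#'   `lambda`.
#' @examples
#' geo <- ventricle_geometry()
#' update_geometry(geo, lv_length = 1.2 * geo$l_v0)
#' @export
update_geometry <- function(geometry, volume = NULL, lv_length = NULL) {
  stopifnot(inherits(geometry, "cardio_geometry"))
  if (is.null(volume) == is.null(lv_length)) {
    abort("supply exactly one of `volume` or `lv_length`")
  }
  s <- if (!is.null(volume)) {
    if (!is.finite(volume) || volume <= 0) abort("cavity volume must be positive")
    sqrt(volume / geometry$v0)
  } else {
    if (!is.finite(lv_length) || lv_length <= 0) abort("boundary length must be positive")
    lv_length / geometry$l_v0
  }
  circ <- s * geometry$circ0
  half_sl <- circ / geometry$n_half_sl
  tibble(ring = seq_len(geometry$n_rings), circumference = circ,
         half_sl = half_sl,
         lambda = stretch_ratio(half_sl, geometry$half_sl0))
}

#' Loading conditions for a ventricle run
#'
#' Preload is the initial uniform stretch of the wall before stimulation,
#' given as percent increase over the reference length (0/10/15/20/25
#' percent correspond to stretch ratios 1.00 to 1.25).  Afterload is a
#' two-element Windkessel behind a resistive aortic valve; filling is a
#' constant-pressure source behind a resistive mitral valve (effectively
#' closed during a fixed-preload beat with the default large filling
#' resistance).
#'
#' @param preload Preload as percent of the reference length (>= 0).
#' @param filling_pressure Constant venous filling pressure (mmHg).
#' @param r_valve Aortic valve resistance (mmHg ms/mL).
#' @param r_peripheral Peripheral resistance (mmHg ms/mL).
#' @param c_arterial Arterial compliance (mL/mmHg).
#' @param p_arterial0 Initial arterial pressure (mmHg).
#' @param r_filling Mitral (filling) resistance (mmHg ms/mL).
#' @return A list with class `cardio_loading`; `$lambda` is the preload
#'   stretch ratio.
#' @export
loading_conditions <- function(preload = 0, filling_pressure = 10,
                               r_valve = 25, r_peripheral = 1500,
                               c_arterial = 1.0, p_arterial0 = 80,
                               r_filling = 1e7) {
  if (!is.finite(preload) || preload < 0) {
    abort("preload must be a non-negative percentage")
  }
  structure(list(
    preload = preload, lambda = 1 + preload / 100,
    filling_pressure = filling_pressure, r_valve = r_valve,
    r_peripheral = r_peripheral, c_arterial = c_arterial,
    p_arterial0 = p_arterial0, r_filling = r_filling
  ), class = "cardio_loading")
}

#' Wall-mechanics parameters
#'
#' Ring wall tension is `k_active` times the ring-average normalized
#' myofilament force plus an exponential passive term, and cavity pressure
#' is the axially weighted mean of tension over radius (thin-wall hoop
#' relation).  `kappa` sets the strength of the constant-volume
#' redistribution of circumference between rings toward force balance
#' (early-activated rings shorten, quiescent rings are pre-stretched);
#' `tau_delta` damps it.  Set `kappa = 0` for strictly uniform wall
#' deformation.
#'
#' @param k_active Active tension scale (mmHg mm per normalized force unit).
#' @param k_passive Passive tension scale (mmHg mm).
#' @param beta_passive Passive stiffness steepness (per unit stretch).
#' @param kappa Redistribution gain (1/ms).
#' @param tau_delta Redistribution damping time constant (ms).
#' @return A list with class `cardio_mechanics`.
#' @export
mechanics_params <- function(k_active = 15000, k_passive = 60,
                             beta_passive = 8, kappa = 0.0005,
                             tau_delta = 120) {
  v <- c(k_active, k_passive, beta_passive, kappa, tau_delta)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("mechanics parameters must be finite and non-negative")
  }
  structure(list(k_active = k_active, k_passive = k_passive,
                 beta_passive = beta_passive, kappa = kappa,
                 tau_delta = tau_delta),
            class = "cardio_mechanics")
}

#' Tissue stimulus specification
#'
#' The standard tissue protocol applies the stimulus for 6 ms at the
#' predetermined apex element(s).  `site = "apex_ring"` stimulates every
#' element of the apical ring (an apical-cap stimulus yielding a symmetric
#' apex-to-base wave); `site = "apex_node"` stimulates the single apex
#' element.  The default amplitude is the frozen result of the one-time
#' calibration that places the activation of the stimulated element
#' (upstroke crossing of -60 mV) at 4.4 ms at resting length (see
#' [calibrate_tissue_stimulus()]).
#'
#' @param amplitude Current density (pA/pF).
#' @param onset Stimulus onset (ms).
#' @param duration Pulse width (ms).
#' @param site `"apex_ring"`, `"apex_node"`, or an integer vector of node
#'   indices (1-based, ring-major).
#' @return A list with class `cardio_tissue_stimulus`.
#' @export
tissue_stimulus <- function(amplitude = 7.704, onset = 0, duration = 6,
                            site = "apex_ring") {
  if (!is.finite(duration) || duration <= 0) abort("stimulus duration must be positive")
  structure(list(amplitude = amplitude, onset = onset, duration = duration,
                 site = site),
            class = "cardio_tissue_stimulus")
}

stim_node_index <- function(stim, geometry) {
  if (is.numeric(stim$site)) {
    idx <- as.integer(stim$site)
  } else if (identical(stim$site, "apex_ring")) {
    idx <- seq_len(geometry$nodes_per_ring)
  } else if (identical(stim$site, "apex_node")) {
    idx <- geometry$apex_index
  } else {
    abort("unknown stimulus site")
  }
  if (any(idx < 1 | idx > geometry$n_rings * geometry$nodes_per_ring)) {
    abort("stimulus node index out of range")
  }
  idx
}

#' Simulate the contracting ventricle with mechano-electric feedback
#'
#' Full coupled run.  Per time step: monodomain electrophysiology with the
#' stretch-activated current evaluated at each ring's stretch ratio;
#' myofilament force from each element's calcium transient at the ring's
#' prescribed half-sarcomere length; ring force to wall tension to cavity
#' pressure; flows through the valves against the Windkessel afterload
#' update the cavity volume; and the new boundary length sets the
#' half-sarcomere lengths and stretch ratios used by the next
#' electrophysiology step (one-step-lagged feedback).
#'
#' The initial state is a single-cell steady state (by default 10
#' conditioning beats at 1 Hz at resting length with the channel enabled)
#' broadcast to all elements; the preload stretch is applied at t = 0,
#' together with the apex stimulus.
#'
#' @param geometry A [ventricle_geometry()] object.
#' @param loading A [loading_conditions()] object.
#' @param cell A [cell_params()] object.
#' @param sac A [sac_params()] object or `NULL` to disable stretch feedback
#'   on the electrics.
#' @param sarc A [sarcomere_params()] object.
#' @param mech A [mechanics_params()] object.
#' @param stim A [tissue_stimulus()] object.
#' @param d_coeff Diffusion coefficient (mm^2/ms); the default is the
#'   frozen calibration value (see [calibrate_tissue_stimulus()]).
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param stride Output sampling interval (ms).
#' @param init Initial cell state; `NULL` runs the conditioning protocol.
#' @param prepace Conditioning beats for the default initial state.
#' @param freeze_geometry Keep the stretch field fixed at the preload value
#'   (no mechanical feedback); useful for isolating the electrics.
#' @return An object of class `ventricle_sim`: list with `time` (ms), `vm`
#'   (time x node matrix, mV), `lambda` and `force` (time x ring), `pv`
#'   (tibble time/volume/pressure/p_art), the geometry and all settings.
#' @examples
#' \donttest{
#' geo <- ventricle_geometry(n_rings = 8, nodes_per_ring = 8)
#' sim <- simulate_ventricle(geo, duration = 80, prepace = 1)
#' }
#' @export
simulate_ventricle <- function(geometry = ventricle_geometry(),
                               loading = loading_conditions(),
                               cell = cell_params(), sac = sac_params(),
                               sarc = sarcomere_params(),
                               mech = mechanics_params(),
                               stim = tissue_stimulus(), d_coeff = 1.4,
                               duration = 700, dt = 0.02, stride = 1,
                               init = NULL, prepace = 10,
                               freeze_geometry = FALSE) {
  stopifnot(inherits(geometry, "cardio_geometry"),
            inherits(loading, "cardio_loading"),
            inherits(mech, "cardio_mechanics"),
            inherits(stim, "cardio_tissue_stimulus"))
  if (is.null(init)) {
    init <- cell_state()
    if (prepace > 0) {
      init <- equilibrate_cell(cell, sac = sac, lambda = 1,
                               duration = prepace * 1000, dt = dt,
                               stim = stimulus_spec(period = 1000),
                               init = init)
    }
  }
  init <- validate_cell_state(init)
  g <- coupling_coefficients(geometry, d_coeff)
  nl0 <- sarcomere_state(loading$lambda * geometry$half_sl0, sarc)
  mech_vec <- c(mech$k_active, mech$k_passive, mech$beta_passive,
                loading$filling_pressure, loading$r_valve,
                loading$r_peripheral, loading$c_arterial,
                loading$p_arterial0, loading$r_filling, mech$kappa,
                mech$tau_delta)
  nodes <- stim_node_index(stim, geometry)
  res <- cpp_run_ventricle(
    geometry$n_rings, geometry$nodes_per_ring, geometry$r0, geometry$dz,
    geometry$half_sl0, geometry$v0, g$g_ring, g$g_ax,
    init, as_par_vector(cell), as_sac_vector(sac),
    as.numeric(nl0), as_nl_par_vector(sarc), mech_vec,
    loading$lambda, stim$amplitude, stim$onset, stim$duration,
    as.integer(nodes - 1L), duration, dt, stride, freeze_geometry)
  structure(list(
    time = res$time, vm = res$vm, lambda = res$lambda, force = res$force,
    pv = tibble(time = res$time, volume = res$volume,
                pressure = res$pressure, p_art = res$p_art),
    geometry = geometry, loading = loading, cell = cell, sac = sac,
    sarc = sarc, mech = mech, stim = stim, d_coeff = d_coeff, dt = dt,
    stride = stride, freeze_geometry = freeze_geometry
  ), class = "ventricle_sim")
}

#' @export
print.ventricle_sim <- function(x, ...) {
  cat(sprintf(
    "<ventricle_sim> %d rings x %d nodes, preload %.0f%%, %.0f ms at dt %.3g ms\n",
    x$geometry$n_rings, x$geometry$nodes_per_ring, x$loading$preload,
    max(x$time), x$dt))
  invisible(x)
}

#' Long-format voltage traces of a ventricle run
#'
#' @param x A `ventricle_sim` object.
#' @param ... Unused.
#' @return A tibble `node`, `ring`, `time`, `vm`, `lambda`.
#' @export
tidy.ventricle_sim <- function(x, ...) {
  npr <- x$geometry$nodes_per_ring
  nnode <- ncol(x$vm)
  nt <- length(x$time)
  ring_of_node <- rep(seq_len(x$geometry$n_rings), each = npr)
  ring_row <- rep(ring_of_node, each = nt)
  tibble(
    node = rep(seq_len(nnode), each = nt),
    ring = ring_row,
    time = rep(x$time, nnode),
    vm = as.numeric(x$vm),        # column-major: node-blocks of length nt
    lambda = as.numeric(x$lambda)[(ring_row - 1) * nt +
                                    rep(seq_len(nt), nnode)]
  )
}

#' Pressure-volume loop and summary haemodynamics
#'
#' Extracts the pressure-volume trajectory of a run, closes the loop with
#' the constant-pressure filling limb back to the end-diastolic volume,
#' and computes stroke volume (EDV - ESV), ejection fraction, and peak
#' pressure.
#'
#' @param sim A [simulate_ventricle()] result (needs at least one complete
#'   ejection cycle, i.e. the volume trace must have passed its minimum).
#' @return A tibble `time`, `volume`, `pressure`, `phase` with class
#'   `cardio_pv`; summary scalars in attributes (see [glance.cardio_pv()]).
#' @export
generate_pv_loop <- function(sim) {
  stopifnot(inherits(sim, "ventricle_sim"))
  pv <- sim$pv
  imin <- which.min(pv$volume)
  if (imin <= 1 || imin == nrow(pv)) {
    if (max(pv$volume) - min(pv$volume) > 1e-9 * max(pv$volume)) {
      abort("incomplete cycle: the volume trace has not passed its minimum")
    }
  }
  edv <- pv$volume[1]
  esv <- min(pv$volume)
  loop <- pv |>
    mutate(phase = dplyr::case_when(
      .data$time <= pv$time[imin] & .data$volume > esv + 1e-12 ~
        ifelse(dplyr::lag(.data$volume, default = edv) - .data$volume > 1e-12,
               "ejection", "isovolumic_contraction"),
      .data$time <= pv$time[imin] ~ "ejection",
      TRUE ~ "relaxation"
    )) |>
    select("time", "volume", "pressure", "phase")
  # filling limb closing the loop at the venous pressure
  fill <- tibble(
    time = NA_real_,
    volume = seq(esv, edv, length.out = 25),
    pressure = sim$loading$filling_pressure,
    phase = "filling"
  )
  out <- bind_rows(loop, fill)
  structure(out,
            class = c("cardio_pv", class(tibble())),
            edv = edv, esv = esv, stroke_volume = edv - esv,
            ejection_fraction = (edv - esv) / edv,
            peak_pressure = max(pv$pressure))
}

#' One-row haemodynamic summary of a pressure-volume loop
#'
#' @param x A [generate_pv_loop()] result.
#' @param ... Unused.
#' @return A tibble with `edv`, `esv`, `stroke_volume`,
#'   `ejection_fraction`, `peak_pressure`.
#' @export
glance.cardio_pv <- function(x, ...) {
  tibble(edv = attr(x, "edv"), esv = attr(x, "esv"),
         stroke_volume = attr(x, "stroke_volume"),
         ejection_fraction = attr(x, "ejection_fraction"),
         peak_pressure = attr(x, "peak_pressure"))
}

#' Calibrate the tissue stimulus amplitude
#'
#' One-time calibration procedure for the two tissue-level free constants.
#' The diffusion coefficient is fixed first (from the target conduction
#' delay per element); this routine then bisects the apex stimulus
#' amplitude until the stimulated element's upstroke crosses -60 mV at the
#' target activation time at resting length.  The resulting amplitude is
#' frozen as the [tissue_stimulus()] default and reused, unchanged, for
#' every preload and disease condition.
#'
#' @param geometry,cell,sac,sarc,mech,d_coeff As in [simulate_ventricle()].
#' @param target_at Target activation time of the stimulated element (ms).
#' @param lower,upper Bisection bracket for the amplitude (pA/pF).
#' @param tol Convergence tolerance on the activation time (ms).
#' @param init Optional pre-equilibrated cell state (computed if `NULL`).
#' @return The calibrated amplitude (pA/pF), with the achieved activation
#'   time as attribute `at`.
#' @export
calibrate_tissue_stimulus <- function(geometry = ventricle_geometry(),
                                      cell = cell_params(),
                                      sac = sac_params(),
                                      sarc = sarcomere_params(),
                                      mech = mechanics_params(),
                                      d_coeff = 1.4, target_at = 4.4,
                                      lower = 2, upper = 200, tol = 0.02,
                                      init = NULL) {
  if (is.null(init)) {
    init <- equilibrate_cell(cell, sac = sac, lambda = 1, duration = 10000,
                             stim = stimulus_spec(period = 1000))
  }
  at_for <- function(amp) {
    sim <- simulate_ventricle(
      geometry, loading_conditions(0), cell, sac, sarc, mech,
      tissue_stimulus(amplitude = amp), d_coeff = d_coeff,
      duration = 12, stride = 0.1, init = init, prepace = 0)
    apex <- tibble(time = sim$time, vm = sim$vm[, geometry$apex_index])
    detect_at(apex)
  }
  lo <- lower; hi <- upper
  at_lo <- at_for(lo)
  if (!is.na(at_lo) && at_lo < target_at) {
    abort("lower bracket already activates earlier than the target")
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    at_mid <- at_for(mid)
    if (is.na(at_mid) || at_mid > target_at) lo <- mid else hi <- mid
    if (!is.na(at_mid) && abs(at_mid - target_at) < tol) {
      return(structure(mid, at = at_mid))
    }
  }
  structure((lo + hi) / 2, at = at_for((lo + hi) / 2))
}
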