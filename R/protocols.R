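provenance_header <- function(settings) {
  c("# cardiomef output",
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("cardiomef"))),
    sprintf("# generated: deterministic (no RNG)"),
    vapply(names(settings), function(n) {
      sprintf("# %s: %s", n, paste(format(settings[[n]], digits = 10),
                                   collapse = " "))
    }, character(1)))
}

write_output_csv <- function(df, path, settings) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(settings), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Single-cell steady-stretch protocol
#'
#' Simulates the paced mid-myocardial cell at each requested steady
#' stretch ratio (52 pA/pF, 1 ms stimulus after 1 Hz conditioning) and
#' extracts the activation/recovery markers of every trace.  All traces
#' share one time grid.
#'
#' @param lambdas Stretch ratios to simulate (non-empty).
#' @param hf Apply the heart-failure remodeling factors.
#' @param sac SAC parameters; enabled by default.
#' @param stim Stimulus ([stimulus_spec()]).
#' @param duration,dt,stride,prepace As in [run_paced_cell()].
#' @param hf_mods Heart-failure factors used when `hf = TRUE`.
#' @param out_dir Optional directory; traces and markers are written as
#'   CSV with a provenance header.
#' @return List with `traces` (long tibble `lambda`, `time`, `vm`, `cai`)
#'   and `markers` (tibble `lambda`, `at`, `rt`, `apd`,
#'   `repolarization_failed`).
#' @export
run_single_cell_stretch <- function(lambdas = c(1.00, 1.10, 1.20, 1.25, 1.30),
                                    hf = FALSE, sac = sac_params(),
                                    stim = stimulus_spec(), duration = 1000,
                                    dt = 0.02, stride = 0.5, prepace = 10,
                                    hf_mods = hf_modifiers(),
                                    out_dir = NULL) {
  if (length(lambdas) == 0) abort("`lambdas` must be non-empty")
  params <- if (hf) apply_hf(cell_params(), hf_mods) else cell_params()
  runs <- purrr::map(lambdas, function(lam) {
    run_paced_cell(params, stim, sac = sac, lambda = lam,
                   duration = duration, dt = dt, stride = stride,
                   prepace = prepace)
  })
  traces <- purrr::map2(runs, lambdas, function(tr, lam) {
    mutate(as_tibble(tr), lambda = lam, .before = 1)
  }) |> bind_rows()
  markers <- purrr::map2(runs, lambdas, function(tr, lam) {
    at <- detect_at(tr, t0 = stim$onset)
    rt <- if (is.na(at)) NA_real_ else detect_rt(tr, after = at)
    tibble(lambda = lam, at = at, rt = rt, apd = rt - at,
           repolarization_failed = !is.na(at) & is.na(rt))
  }) |> bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    settings <- list(protocol = "single_cell_stretch", lambdas = lambdas,
                     hf = hf, dt = dt, stride = stride, duration = duration,
                     stim_amplitude = stim$amplitude,
                     stim_duration = stim$duration,
                     g_sac = sac$g_sac)
    write_output_csv(traces, file.path(out_dir, "single_cell_traces.csv"),
                     settings)
    write_output_csv(markers, file.path(out_dir, "single_cell_markers.csv"),
                     settings)
  }
  list(traces = traces, markers = markers)
}

#' Ventricle preload protocol
#'
#' Runs the contracting-ventricle simulation at each preload (percent of
#' the reference length) for the requested condition arms and summarizes
#' the per-fiber APD extrema in the shape of the published comparison
#' table: one row per stretch ratio, minimum and maximum APD for control
#' and heart failure, `NA` on repolarization failure.
#'
#' @param preloads Preload percentages (0 = resting length).
#' @param conditions Character subset of `c("control", "hf")`.
#' @param geometry,cell,sac,sarc,mech,stim,d_coeff,duration,dt,stride As in
#'   [simulate_ventricle()].
#' @param hf_mods Heart-failure factors for the `"hf"` arm.
#' @param out_dir Optional output directory (CSV with provenance header).
#' @param keep_sims Also return the raw simulation objects.
#' @param progress Emit a message as each run completes.
#' @return A tibble `stretch_ratio`, `min_apd_control`, `min_apd_hf`,
#'   `max_apd_control`, `max_apd_hf` (columns for arms not run are `NA`),
#'   with the per-run marker summaries in attribute `summaries` and,
#'   optionally, `sims`.
#' @export
run_ventricle_preload <- function(preloads = c(0, 10, 15, 20, 25),
                                  conditions = c("control", "hf"),
                                  geometry = ventricle_geometry(),
                                  cell = cell_params(), sac = sac_params(),
                                  sarc = sarcomere_params(),
                                  mech = mechanics_params(),
                                  stim = tissue_stimulus(), d_coeff = 1.4,
                                  duration = 700, dt = 0.02, stride = 1,
                                  hf_mods = hf_modifiers(), out_dir = NULL,
                                  keep_sims = FALSE, progress = FALSE) {
  if (length(preloads) == 0) abort("`preloads` must be non-empty")
  conditions <- match.arg(conditions, c("control", "hf"), several.ok = TRUE)
  arms <- list()
  if ("control" %in% conditions) arms$control <- cell
  if ("hf" %in% conditions) arms$hf <- apply_hf(cell, hf_mods)
  summaries <- list()
  sims <- list()
  for (arm in names(arms)) {
    init <- equilibrate_cell(arms[[arm]], sac = sac, lambda = 1,
                             duration = 10000, dt = dt,
                             stim = stimulus_spec(period = 1000))
    for (pl in preloads) {
      sim <- simulate_ventricle(geometry, loading_conditions(pl),
                                arms[[arm]], sac, sarc, mech, stim,
                                d_coeff = d_coeff, duration = duration,
                                dt = dt, stride = stride, init = init,
                                prepace = 0)
      sm <- summarize_markers(ventricle_markers(sim))
      sm$condition <- arm
      sm$preload <- pl
      summaries[[paste(arm, pl)]] <- sm
      if (keep_sims) sims[[paste(arm, pl)]] <- sim
      if (progress) {
        message(sprintf("%s preload %g%%: min APD %.1f, max APD %.1f, %d failed",
                        arm, pl, sm$min_apd, sm$max_apd, sm$n_failed))
      }
    }
  }
  sm <- bind_rows(summaries)
  wide <- tibble(stretch_ratio = 1 + preloads / 100)
  for (arm in c("control", "hf")) {
    rows <- sm[sm$condition == arm, ][match(preloads,
                                            sm$preload[sm$condition == arm]), ]
    wide[[paste0("min_apd_", arm)]] <-
      if (arm %in% names(arms)) rows$min_apd else NA_real_
    wide[[paste0("max_apd_", arm)]] <-
      if (arm %in% names(arms)) rows$max_apd else NA_real_
  }
  wide <- wide[c("stretch_ratio", "min_apd_control", "min_apd_hf",
                 "max_apd_control", "max_apd_hf")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    settings <- list(protocol = "ventricle_preload", preloads = preloads,
                     conditions = conditions, dt = dt, stride = stride,
                     duration = duration, d_coeff = d_coeff,
                     stim_amplitude = stim$amplitude,
                     n_rings = geometry$n_rings,
                     nodes_per_ring = geometry$nodes_per_ring,
                     g_sac = sac$g_sac)
    write_output_csv(wide, file.path(out_dir, "preload_apd_table.csv"),
                     settings)
    write_output_csv(sm, file.path(out_dir, "preload_marker_summaries.csv"),
                     settings)
  }
  structure(wide, summaries = sm, sims = if (keep_sims) sims)
}

#' Control versus heart-failure comparison
#'
#' Paired 1 Hz steady-state single-cell action potentials and, at the
#' tissue level, fixed-preload pressure-volume loops for the control and
#' heart-failure parameter sets.  Both arms use identical settings except
#' for the six remodeling factors.
#'
#' @param preload Tissue preload percent for the PV-loop comparison.
#' @param hf_mods The remodeling factors.
#' @param geometry,sac,sarc,mech,stim,d_coeff,duration,dt As in
#'   [simulate_ventricle()].
#' @param cell_duration Recorded single-cell duration (ms).
#' @param prepace Conditioning beats for the single-cell comparison.
#' @param out_dir Optional output directory.
#' @return List with `cell` (long tibble `condition`, `time`, `vm`,
#'   `cai`), `cell_markers`, `pv` (long tibble of both loops) and
#'   `haemodynamics` (per-condition [glance.cardio_pv()] rows).
#' @export
run_hf_comparison <- function(preload = 10, hf_mods = hf_modifiers(),
                              geometry = ventricle_geometry(),
                              sac = sac_params(), sarc = sarcomere_params(),
                              mech = mechanics_params(),
                              stim = tissue_stimulus(), d_coeff = 1.4,
                              duration = 700, dt = 0.02,
                              cell_duration = 1000, prepace = 10,
                              out_dir = NULL) {
  arms <- list(control = cell_params(),
               hf = apply_hf(cell_params(), hf_mods))
  cellruns <- purrr::imap(arms, function(p, nm) {
    tr <- run_paced_cell(p, stimulus_spec(), sac = sac, lambda = 1,
                         duration = cell_duration, dt = dt,
                         prepace = prepace)
    mutate(as_tibble(tr), condition = nm, .before = 1)
  })
  cell_long <- bind_rows(cellruns)
  cell_markers <- cell_long |>
    group_by(.data$condition) |>
    summarise(
      at = cross_time(.data$time, .data$vm, -60, +1, from = 0),
      rt = {
        a <- cross_time(.data$time, .data$vm, -60, +1, from = 0)
        if (is.na(a)) NA_real_ else {
          sel <- .data$time >= a
          tpk <- .data$time[sel][which.max(.data$vm[sel])]
          cross_time(.data$time, .data$vm, -60, -1, from = tpk)
        }
      },
      .groups = "drop"
    ) |>
    mutate(apd = .data$rt - .data$at)

  loops <- purrr::imap(arms, function(p, nm) {
    init <- equilibrate_cell(p, sac = sac, lambda = 1, duration = 10000,
                             dt = dt, stim = stimulus_spec(period = 1000))
    sim <- simulate_ventricle(geometry, loading_conditions(preload), p, sac,
                              sarc, mech, stim, d_coeff = d_coeff,
                              duration = duration, dt = dt, init = init,
                              prepace = 0)
    pv <- generate_pv_loop(sim)
    list(pv = mutate(as_tibble(pv), condition = nm, .before = 1),
         gl = mutate(glance(pv), condition = nm, .before = 1))
  })
  pv_long <- bind_rows(purrr::map(loops, "pv"))
  haemo <- bind_rows(purrr::map(loops, "gl"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    settings <- list(protocol = "hf_comparison", preload = preload,
                     dt = dt, duration = duration,
                     hf_factors = unlist(unclass(hf_mods)))
    write_output_csv(cell_long, file.path(out_dir, "hf_cell_traces.csv"),
                     settings)
    write_output_csv(pv_long, file.path(out_dir, "hf_pv_loops.csv"),
                     settings)
    write_output_csv(haemo, file.path(out_dir, "hf_haemodynamics.csv"),
                     settings)
  }
  list(cell = cell_long, cell_markers = cell_markers, pv = pv_long,
       haemodynamics = haemo)
}
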