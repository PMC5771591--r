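#' Default configuration
#'
#' All tunable parameters of the simulator as a nested list, matching the
#' YAML schema of [read_config()]: sections `cell`, `hf`, `sac`,
#' `sarcomere`, `geometry`, `loading`, `mechanics`, `stimulus` (single
#' cell), `tissue_stimulus`, and `numerics`.
#'
#' @return A named list.
#' @export
default_config <- function() {
  drop_class <- function(x) {
    x <- unclass(x)
    x[vapply(x, is.numeric, logical(1)) | vapply(x, is.character, logical(1))]
  }
  list(
    cell = drop_class(cell_params()),
    hf = drop_class(hf_modifiers()),
    sac = drop_class(sac_params()),
    sarcomere = drop_class(sarcomere_params()),
    geometry = list(n_rings = 20, nodes_per_ring = 24, base_radius = 29.8,
                    apex_base_length = 53.7, half_sl0 = 0.97),
    loading = drop_class(loading_conditions()),
    mechanics = drop_class(mechanics_params()),
    stimulus = list(amplitude = 52, onset = 0, duration = 1),
    tissue_stimulus = list(amplitude = tissue_stimulus()$amplitude,
                           onset = 0, duration = 6, site = "apex_ring"),
    numerics = list(dt = 0.02, stride = 1, d_coeff = 1.4,
                    duration_cell = 1000, duration_tissue = 700,
                    prepace_beats = 10)
  )
}

#' Read / write a simulator configuration
#'
#' Configurations are plain YAML mirroring [default_config()]; unknown
#' keys raise an error, omitted keys keep their defaults.
#'
#' @param path File path.
#' @return `read_config()`: the merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  extra <- setdiff(names(user), names(base))
  if (length(extra) > 0) {
    abort(sprintf("unknown configuration section(s): %s",
                  paste(extra, collapse = ", ")))
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad) > 0) {
      abort(sprintf("unknown key(s) in section '%s': %s", sec,
                    paste(bad, collapse = ", ")))
    }
    base[[sec]] <- modifyList(base[[sec]], user[[sec]])
  }
  base
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build parameter objects from a configuration list
#'
#' @param config A configuration list from [read_config()] or
#'   [default_config()].
#' @return A list of constructed parameter objects (`cell`, `hf_mods`,
#'   `sac`, `sarc`, `geometry`, `loading`, `mech`, `stim`, `tissue_stim`,
#'   `numerics`).
#' @export
config_objects <- function(config = default_config()) {
  list(
    cell = do.call(cell_params, config$cell),
    hf_mods = do.call(hf_modifiers, config$hf),
    sac = do.call(sac_params, config$sac),
    sarc = do.call(sarcomere_params, config$sarcomere),
    geometry = do.call(ventricle_geometry, config$geometry),
    loading = do.call(loading_conditions,
                      config$loading[setdiff(names(config$loading), "lambda")]),
    mech = do.call(mechanics_params, config$mechanics),
    stim = do.call(stimulus_spec, config$stimulus),
    tissue_stim = do.call(tissue_stimulus, config$tissue_stimulus),
    numerics = config$numerics
  )
}
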