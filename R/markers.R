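coerce_trace <- function(trace) {
  if (is.data.frame(trace)) {
    if (!all(c("time", "vm") %in% names(trace))) {
      abort("a voltage trace needs `time` and `vm` columns")
    }
    trace <- trace[c("time", "vm")]
  } else {
    abort("`trace` must be a data frame with `time` and `vm` columns")
  }
  if (nrow(trace) == 0) abort("empty voltage trace")
  trace
}

cross_time <- function(time, vm, threshold, direction, from = -Inf) {
  ok <- time >= from
  time <- time[ok]; vm <- vm[ok]
  if (length(time) < 2) return(NA_real_)
  if (direction > 0) {
    hit <- which(vm[-length(vm)] < threshold & vm[-1] >= threshold)
  } else {
    hit <- which(vm[-length(vm)] >= threshold & vm[-1] < threshold)
  }
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  # linear interpolation between the bracketing samples
  time[i] + (threshold - vm[i]) / (vm[i + 1] - vm[i]) * (time[i + 1] - time[i])
}

#' Local activation time of a voltage trace
#'
#' The activation time (AT) is the first upward crossing of the threshold
#' (-60 mV by default) after `t0`, linearly interpolated between samples.
#' Returns `NA` if the trace never crosses.
#'
#' @param trace Data frame with `time` (ms) and `vm` (mV), uniformly
#'   sampled.
#' @param threshold Crossing threshold (mV).
#' @param t0 Search start, typically the stimulus onset (ms).
#' @return AT in ms, or `NA`.
#' @examples
#' tr <- tibble::tibble(time = 0:20, vm = -80 + 2 * time)
#' detect_at(tr)   # 10
#' @export
detect_at <- function(trace, threshold = -60, t0 = 0) {
  trace <- coerce_trace(trace)
  cross_time(trace$time, trace$vm, threshold, +1, from = t0)
}

#' Local recovery time of a voltage trace
#'
#' The recovery time (RT) is the first downward crossing of the threshold
#' (-60 mV, typically about 80 percent of repolarization) after the action
#' potential peak, linearly interpolated.  Starting the search at the peak
#' avoids spurious downward crossings of the stimulus artifact.  Returns
#' `NA` when the membrane never repolarizes below the threshold
#' (repolarization failure).
#'
#' @inheritParams detect_at
#' @param after Search only after this time (ms); normally the activation
#'   time.  The search itself starts at the post-`after` voltage peak.
#' @return RT in ms, or `NA`.
#' @export
detect_rt <- function(trace, threshold = -60, after = 0) {
  trace <- coerce_trace(trace)
  if (is.na(after)) abort("`after` (the activation time) must be defined")
  sel <- trace$time >= after
  if (!any(sel)) return(NA_real_)
  tpk <- trace$time[sel][which.max(trace$vm[sel])]
  cross_time(trace$time, trace$vm, threshold, -1, from = tpk)
}

#' Action potential duration
#'
#' APD = RT - AT, reported as APD80 (the -60 mV threshold corresponds to
#' roughly 80 percent repolarization).
#'
#' @param at Activation time (ms).
#' @param rt Recovery time (ms).
#' @return APD in ms.
#' @examples
#' apd(4.4, 353.3)
#' @export
apd <- function(at, rt) {
  if (any(!is.na(at) & !is.na(rt) & rt <= at)) {
    abort("recovery must occur after activation (rt > at)")
  }
  rt - at
}

#' Per-fiber activation/recovery markers
#'
#' Computes AT, RT, and APD for every fiber in a long-format voltage data
#' frame.  Fibers whose membrane never crosses the threshold upward have
#' no markers; fibers that activate but never repolarize below the
#' threshold are flagged as repolarization failures (RT and APD
#' undefined).
#'
#' @param data Long tibble with columns `time`, `vm`, and a fiber
#'   identifier column (default `fiber`; `node` is used if present), e.g.
#'   from [tidy.ventricle_sim()].  A plain single trace without an
#'   identifier column is treated as one fiber.
#' @param threshold Marker threshold (mV).
#' @param t0 Stimulus onset (ms).
#' @return A tibble (`marker_table`) with `fiber`, `at`, `rt`, `apd`,
#'   `repolarization_failed`.
#' @export
extract_markers <- function(data, threshold = -60, t0 = 0) {
  if (!is.data.frame(data) || nrow(data) == 0) abort("empty voltage data")
  if (!all(c("time", "vm") %in% names(data))) {
    abort("`data` needs `time` and `vm` columns")
  }
  if (!any(c("fiber", "node") %in% names(data))) data$fiber <- 1L
  id <- if ("fiber" %in% names(data)) "fiber" else "node"
  out <- data |>
    group_by(fiber = .data[[id]]) |>
    summarise(
      at = cross_time(.data$time, .data$vm, threshold, +1, from = t0),
      rt = {
        a <- cross_time(.data$time, .data$vm, threshold, +1, from = t0)
        if (is.na(a)) NA_real_ else {
          sel <- .data$time >= a
          tpk <- .data$time[sel][which.max(.data$vm[sel])]
          cross_time(.data$time, .data$vm, threshold, -1, from = tpk)
        }
      },
      .groups = "drop"
    ) |>
    mutate(
      apd = .data$rt - .data$at,
      repolarization_failed = !is.na(.data$at) & is.na(.data$rt)
    )
  class(out) <- c("marker_table", class(out))
  out
}

#' Markers of a ventricle run
#'
#' Convenience wrapper: per-element markers of a [simulate_ventricle()]
#' result, with the element's ring attached.
#'
#' @param sim A `ventricle_sim` object.
#' @inheritParams extract_markers
#' @return A `marker_table` tibble with an extra `ring` column.
#' @export
ventricle_markers <- function(sim, threshold = -60, t0 = NULL) {
  stopifnot(inherits(sim, "ventricle_sim"))
  t0 <- t0 %||% sim$stim$onset
  long <- tidy(sim)
  mk <- extract_markers(dplyr::rename(long, fiber = "node"), threshold, t0)
  ring <- rep(seq_len(sim$geometry$n_rings),
              each = sim$geometry$nodes_per_ring)
  mk$ring <- ring[mk$fiber]
  mk
}

#' Global marker summary
#'
#' Minima/maxima of the per-fiber markers: earliest/latest activation,
#' first/last recovery, minimum/maximum APD.  Fibers that failed to
#' repolarize are excluded from the recovery and APD extrema and counted;
#' if every activated fiber failed, the summary carries `NA` markers.
#'
#' @param markers A [extract_markers()] result.
#' @return A one-row tibble: `n_fibers`, `n_activated`, `n_failed`,
#'   `earliest_at`, `latest_at`, `first_rt`, `last_rt`, `min_apd`,
#'   `max_apd`.
#' @export
summarize_markers <- function(markers) {
  if (!is.data.frame(markers) || nrow(markers) == 0) {
    abort("need at least one fiber")
  }
  act <- markers[!is.na(markers$at), ]
  ok <- act[!is.na(act$rt), ]
  rng <- function(x, f) if (nrow(ok) == 0) NA_real_ else f(x)
  tibble(
    n_fibers = nrow(markers),
    n_activated = nrow(act),
    n_failed = sum(markers$repolarization_failed),
    earliest_at = if (nrow(act) == 0) NA_real_ else min(act$at),
    latest_at = if (nrow(act) == 0) NA_real_ else max(act$at),
    first_rt = rng(ok$rt, min),
    last_rt = rng(ok$rt, max),
    min_apd = rng(ok$apd, min),
    max_apd = rng(ok$apd, max)
  )
}

#' @rdname summarize_markers
#' @param x A `marker_table`.
#' @param ... Unused.
#' @export
glance.marker_table <- function(x, ...) summarize_markers(x)

#' One-row summary of a ventricle run
#'
#' Markers plus haemodynamics of a [simulate_ventricle()] result.
#'
#' @param x A `ventricle_sim` object.
#' @param ... Unused.
#' @return A one-row tibble combining [summarize_markers()] and
#'   [glance.cardio_pv()] fields.
#' @export
glance.ventricle_sim <- function(x, ...) {
  mk <- summarize_markers(ventricle_markers(x))
  pv <- glance(generate_pv_loop(x))
  dplyr::bind_cols(mk, pv)
}
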