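#' Plot an action-potential trace
#'
#' @param object A `cardio_trace` tibble (or any data frame with `time`
#'   and `vm`); a `lambda` or `condition` column is mapped to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cardio_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$vm))
  if ("lambda" %in% names(object) && length(unique(object$lambda)) > 1) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = factor(.data$lambda))) +
      ggplot2::labs(colour = expression(lambda))
  } else if ("condition" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$condition))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "time (ms)", y = "membrane voltage (mV)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force twitch
#'
#' @param object A [twitch_from_calcium()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cardio_twitch <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$force)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "developed force (normalized)") +
    ggplot2::theme_minimal()
}

#' Plot a pressure-volume loop
#'
#' @param object A [generate_pv_loop()] result (or several row-bound ones
#'   carrying a `condition` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cardio_pv <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$volume, y = .data$pressure))
  if ("condition" %in% names(object)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(colour = .data$condition))
  } else {
    p <- p + ggplot2::geom_path()
  }
  p + ggplot2::labs(x = "cavity volume (mL)", y = "pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' Activation/recovery marker map of a ventricle run
#'
#' Per-element activation time, recovery time, or APD against the ring
#' index (apex to base).
#'
#' @param sim A `ventricle_sim` object.
#' @param what `"at"`, `"rt"` or `"apd"`.
#' @return A ggplot object.
#' @export
plot_marker_map <- function(sim, what = c("at", "rt", "apd")) {
  what <- match.arg(what)
  mk <- ventricle_markers(sim)
  lab <- c(at = "activation time (ms)", rt = "recovery time (ms)",
           apd = "APD (ms)")[[what]]
  ggplot2::ggplot(mk, ggplot2::aes(x = .data$ring, y = .data[[what]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "ring (apex to base)", y = lab) +
    ggplot2::theme_minimal()
}
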