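#' Plot phase-averaged pressures
#'
#' Per-phase means with bootstrap error ribbons, one panel per component,
#' with the overall mean as a dashed reference line.  A flat profile means
#' the pair list is complete; systematic structure across the interval is
#' the missed-interaction signature.
#'
#' @param object A [phase_average()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_average <- function(object, ...) {
  pp <- object$per_phase
  ov <- object$overall
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$phase, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = ov, ggplot2::aes(yintercept = .data$mean),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "phase within update interval (steps after list build)",
                  y = "mean pressure (bar)")
}

#' Plot a Welch power spectrum with list-update harmonics
#'
#' Log-log PSD; when the neighbor-list interval is known, vertical lines
#' mark the harmonics of the update frequency where artifact spikes appear.
#'
#' @param object A [welch_psd()] result.
#' @param flags Optional [detect_nstlist_harmonics()] result to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psd_result <- function(object, flags = NULL, ...) {
  df <- as_tibble(object)[-1, ]  # drop DC for the log axis
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (1/ps)", y = "PSD (bar² ps)")
  if (!is.null(flags) && nrow(flags)) {
    p <- p + ggplot2::geom_vline(data = as_tibble(flags),
                                 ggplot2::aes(xintercept = .data$frequency),
                                 linetype = "dotted", colour = "red")
  }
  p
}

#' Plot running pressure averages of a simulator run
#'
#' Running averages of the diagonal pressure-tensor components under two
#' sampling strides; diverging limits between strides indicate a per-phase
#' pattern, i.e. missed interactions.
#'
#' @param object An [run_ljmd()] result.
#' @param strides Two sampling strides to compare.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ljmd_run <- function(object, strides = c(1L, object$schedule$nstlist),
                              ...) {
  dt <- object$schedule$dt
  comp <- object$pressure[, c("step", "Pxx", "Pyy", "Pzz")]
  dfs <- purrr::map(strides, function(s) {
    ra <- running_average(comp, stride = s, dt = dt)
    tidyr::pivot_longer(ra, c("Pxx", "Pyy", "Pzz"),
                        names_to = "component", values_to = "running_mean") %>%
      mutate(stride = paste0("stride ", s))
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(x = .data$time, y = .data$running_mean,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stride) +
    ggplot2::labs(x = "time (ps)", y = "running mean pressure (bar)")
}

#' Plot a membrane height field
#'
#' @param object A [height_field()].
#' @param what `"height"` or `"curvature"` (local mean curvature).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.height_field <- function(object, what = c("height", "curvature"), ...) {
  what <- match.arg(what)
  m <- if (what == "height") object$h else mean_curvature(object)
  df <- expand.grid(x = (seq_len(nrow(m)) - 1) * object$dx,
                    y = (seq_len(ncol(m)) - 1) * object$dy)
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  fill = if (what == "height") "h (nm)" else "H (1/nm)")
}
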