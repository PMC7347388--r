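#' Plot a spike-triggered force-velocity histogram
#'
#' Tile plot of log-scaled counts with the mass-weighted centroid marked
#' by a cross, matching how recruitment regimes are usually displayed.
#'
#' @param object An `fm_hist2d`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fm_hist2d <- function(object, ...) {
  fe <- object$force_edges
  ve <- object$velocity_edges
  df <- tidyr::expand_grid(
    fi = seq_len(length(fe) - 1L),
    vi = seq_len(length(ve) - 1L)
  )
  df$force <- (fe[df$fi] + fe[df$fi + 1L]) / 2
  df$velocity <- (ve[df$vi] + ve[df$vi + 1L]) / 2
  df$log_density <- object$log_density[cbind(df$fi, df$vi)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$force, y = .data$velocity,
                                   fill = .data$log_density)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$centroid["force"],
                      y = object$centroid["velocity"],
                      shape = 3, size = 4, colour = "white", stroke = 1.2) +
    ggplot2::scale_fill_viridis_c(name = "log density") +
    ggplot2::labs(x = "probe force (uN)", y = "probe velocity (um/s)")
}

#' Plot a cluster label map
#'
#' @param object An `fm_cluster_map`.
#' @param ... Unused.
#' @return A ggplot with one colour per cluster; background omitted.
#' @export
autoplot.fm_cluster_map <- function(object, ...) {
  lab <- object$labels
  df <- tibble::tibble(
    row = rep(seq_len(nrow(lab)), ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    cluster = as.vector(lab)
  )
  df <- df[df$cluster > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "cluster") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a force-per-spike curve
#'
#' @param object An `fm_force_curve`.
#' @param ... Unused.
#' @return A ggplot of peak force vs spike count with the linear fit.
#' @export
autoplot.fm_force_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$n_spikes,
                                    y = .data$peak_force_uN)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "number of spikes", y = "peak average force (uN)")
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_abline(intercept = coef(object$fit)[1L],
                                  slope = coef(object$fit)[2L],
                                  linetype = 2)
  }
  p
}

#' Plot cluster calcium traces
#'
#' @param traces An `fm_cluster_traces` tibble.
#' @return A ggplot of dF/F over time, one facet per cluster; invalid
#'   (occluded) frames are omitted.
#' @export
plot_cluster_traces <- function(traces) {
  df <- traces[traces$valid, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster)) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F))
}

#' Overlay detected spikes on a trace
#'
#' @param trace Raw trace.
#' @param fs Sampling rate (Hz).
#' @param spikes An `fm_spikes` tibble from [detect_spikes()].
#' @param xlim_s Optional two-element time window (s).
#' @return A ggplot with spike peaks and onsets marked.
#' @export
plot_spike_overlay <- function(trace, fs, spikes, xlim_s = NULL) {
  tt <- (seq_along(trace) - 1) / fs
  df <- tibble::tibble(time_s = tt, v = as.numeric(trace))
  if (!is.null(xlim_s)) {
    df <- df[df$time_s >= xlim_s[1L] & df$time_s <= xlim_s[2L], ]
    spikes <- spikes[spikes$peak_s >= xlim_s[1L] & spikes$peak_s <= xlim_s[2L], ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = spikes$peak_s, colour = "red",
                        alpha = 0.5) +
    ggplot2::geom_point(data = tibble::tibble(
      time_s = spikes$onset_s,
      v = df$v[match(round(spikes$onset_s * fs) + 1L,
                     round(df$time_s * fs) + 1L)]
    ), colour = "blue", size = 1, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "trace")
}
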