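#' @export
plot.fplr_calcium_trace <- function(x, ..., thresholds = NULL) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (ms)", ylab = "calcium (a.u.)", ...)
  if (!is.null(thresholds)) {
    th <- as_thresholds(thresholds)
    graphics::abline(h = th$theta_d, lty = 2, col = "blue")
    graphics::abline(h = th$theta_p, lty = 2, col = "red")
  }
  invisible(x)
}

#' @export
plot.fplr_weight_trajectory <- function(x, ...) {
  graphics::plot(trace_times(x), x$values, type = "l",
                 xlab = "time (ms)", ylab = "weight", ...)
  invisible(x)
}

#' @export
plot.fplr_btsp_session <- function(x, laps = seq_len(x$laps), ...) {
  old <- graphics::par(mfrow = c(length(laps), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (l in laps) {
    v <- lap_voltage(x, l)
    graphics::plot((seq_along(v) - 1L) * x$dt / 1000, v, type = "l",
                   xlab = "", ylab = sprintf("lap %d (mV)", l), ...)
  }
  invisible(x)
}

#' Heatmap of a phase-plane grid
#'
#' @param pp output of [phase_plane()].
#' @param ... passed to [graphics::image()].
#' @export
plot_phase_plane <- function(pp, ...) {
  ca <- sort(unique(pp$ca))
  w <- sort(unique(pp$w))
  z <- matrix(pp$dw[order(pp$w, pp$ca)], nrow = length(ca), ncol = length(w))
  graphics::image(ca, w, z, xlab = "calcium (a.u.)", ylab = "weight",
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(pp)
}
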