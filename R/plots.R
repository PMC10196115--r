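# Minimal base-graphics displays for the main result objects.

#' @export
plot.lfp_ep_waveform <- function(x, sig = NULL, ...) {
  graphics::plot(x$time, x$mean, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "normalized LFP (z)",
                 main = sprintf("EP %s (%s, n = %d)", x$class, x$hemisphere,
                                x$n_trials), ...)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$mean + x$sem, rev(x$mean - x$sem)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::abline(v = 0, lty = 2)
  if (!is.null(sig))
    graphics::points(sig$time[sig$significant],
                     rep(min(x$mean - x$sem), sum(sig$significant)),
                     pch = 16, col = "darkgreen", cex = 0.4)
  invisible(x)
}

#' @export
plot.lfp_scalogram <- function(x, ...) {
  graphics::image(x$time, log2(x$freq), t(x$power),
                  xlab = "time (s)", ylab = "frequency (Hz, log2)",
                  main = sprintf("scalogram (%s, n = %d)", x$normalization,
                                 x$n_trials),
                  col = grDevices::hcl.colors(64, "viridis"), yaxt = "n", ...)
  at <- c(4, 8, 16, 32, 64, 120)
  graphics::axis(2, at = log2(at), labels = at)
  graphics::abline(v = 0, lty = 2, col = "white")
  invisible(x)
}

#' @export
plot.lfp_corr_trace <- function(x, ...) {
  graphics::plot(x$time, x$mean, type = "l", lwd = 2, ylim = c(-1, 1),
                 xlab = "time (s)", ylab = "interhemispheric r",
                 main = sprintf("sliding correlation (%d ms window)",
                                x$window_ms), ...)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$mean + x$sem, rev(x$mean - x$sem)),
                    border = NA, col = grDevices::adjustcolor("grey40", 0.3))
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' @export
plot.lfp_plv_map <- function(x, normalized = TRUE, ...) {
  z <- if (normalized && !is.null(x$plv_norm)) x$plv_norm else x$plv
  graphics::image(x$time, log2(x$freq), t(z),
                  xlab = "time (s)", ylab = "frequency (Hz, log2)",
                  main = sprintf("PLV%s (%d ms window, n = %d)",
                                 if (normalized && !is.null(x$plv_norm))
                                   " (baseline-normalized)" else "",
                                 x$window_ms, x$n_trials),
                  col = grDevices::hcl.colors(64, "viridis"), yaxt = "n", ...)
  at <- c(4, 8, 16, 32, 64, 120)
  graphics::axis(2, at = log2(at), labels = at)
  graphics::abline(v = 0, lty = 2, col = "white")
  invisible(x)
}

#' Display a feature-selection map (bands x time windows)
#' @param map matrix from [feature_selection_map()]
#' @param window_ms window length used for the features (for the time axis)
#' @export
plot_feature_map <- function(map, window_ms = 30, ...) {
  graphics::image(seq_len(ncol(map)) * window_ms, seq_len(nrow(map)), t(map),
                  xlab = "window start (ms)", ylab = "", yaxt = "n",
                  main = "selected features over time and frequency",
                  col = grDevices::hcl.colors(32, "inferno"), ...)
  graphics::axis(2, at = seq_len(nrow(map)), labels = rownames(map), las = 2)
  invisible(map)
}
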