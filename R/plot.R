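#' Spike raster of a simulation run
#'
#' @param x an `snn_run` from [run_network()].
#' @param ... passed to [graphics::plot()].
#' @return The run, invisibly.
#' @export
plot.snn_run <- function(x, ...) {
  ids <- x$net$neurons$id
  yi <- match(x$spikes$neuron, ids)
  graphics::plot(x$spikes$time_ms, yi, pch = "|", yaxt = "n",
                 xlab = "time (ms)", ylab = "", ylim = c(0.5, length(ids) + 0.5),
                 ...)
  axis(2, at = seq_along(ids), labels = ids, las = 1)
  invisible(x)
}

#' Weight trajectories from a long weight log
#'
#' @param weights data.frame with `time_ms`, `synapse`, `w` (from
#'   [run_network()] or a `classical_run`).
#' @param ... passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot_weights <- function(weights, ...) {
  labs <- unique(weights$synapse)
  graphics::plot(range(weights$time_ms) / 1000, c(0, 1), type = "n",
                 xlab = "time (s)", ylab = "w", ...)
  for (i in seq_along(labs)) {
    d <- weights[weights$synapse == labs[i], ]
    lines(d$time_ms / 1000, d$w, col = i, lwd = 2)
  }
  legend("topleft", legend = labs, col = seq_along(labs), lwd = 2, bty = "n")
  invisible(weights)
}

#' Arena trajectory with collision marks
#'
#' @param x an `operant_run`.
#' @param arena_obj the [arena()] the run used (drawn as outline + obstacles).
#' @param ... passed to [graphics::plot()].
#' @return The run, invisibly.
#' @export
plot.operant_run <- function(x, arena_obj = NULL, ...) {
  tr <- x$trajectory
  graphics::plot(tr$x, tr$y, type = "l", asp = 1, xlab = "x (m)",
                 ylab = "y (m)", col = "grey40", ...)
  if (!is.null(arena_obj)) {
    graphics::rect(0, 0, arena_obj$width, arena_obj$height, border = "black")
    for (ob in arena_obj$obstacles)
      polygon(ob, col = "grey80", border = "black")
  }
  if (nrow(x$collisions) > 0)
    points(x$collisions$x, x$collisions$y, pch = 4, col = "red", cex = 1.4,
           lwd = 2)
  invisible(x)
}
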