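#' Default logarithmic time-resolution grid
#'
#' About 30 log-spaced integer window lengths from 2 frames (twice the
#' sampling time) to the full trajectory length, de-duplicated, endpoints
#' forced.
#'
#' @param t_frames trajectory length in frames (>= 4).
#' @param n_points nominal grid size.
#' @return strictly increasing integer vector spanning \[2, t_frames\].
#' @export
delta_t_grid <- function(t_frames, n_points = 30L) {
  stopifnot(t_frames >= 4)
  g <- unique(round(exp(seq(log(2), log(t_frames), length.out = n_points))))
  sort(unique(c(2L, as.integer(g), as.integer(t_frames))))
}

#' Cluster count and unclassified fraction across time resolutions
#'
#' Runs [onion()] at every window length of a (log-spaced) `delta_t` grid,
#' recording the number of detected states and the ENV0 fraction -- the
#' two diagnostic curves that reveal at which time resolutions each
#' environment is resolvable. Scanning removes the a-priori choice of a
#' single time resolution.
#'
#' @param x ensemble accepted by [onion()].
#' @param grid integer vector of window lengths (frames); default
#'   [delta_t_grid()] over the trajectory length.
#' @param ... further arguments passed to [onion()].
#' @return object of class `delta_t_scan`: data.frame with columns
#'   `delta_t_frames`, `delta_t_time`, `n_states`, `env0_fraction`; the
#'   sampling interval is kept in attribute `dt`.
#' @examples
#' sp <- markov_spec(c(-1, 1), 0.1, diag(2))
#' g <- gen_state_ensemble(sp, 30, 200, seed = 1)
#' sc <- delta_t_scan(g$ensemble, grid = c(2, 10, 50, 200))
#' sc
#' @export
delta_t_scan <- function(x, grid = NULL, ...) {
  ens <- as.signal_ensemble(x)
  tt <- dim(ens$values)[2]
  if (tt < 4) stop("need at least 4 frames for a delta_t scan")
  if (is.null(grid)) grid <- delta_t_grid(tt)
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 2) || any(grid > tt)) stop("grid must lie within [2, T]")
  ns <- integer(length(grid)); e0 <- numeric(length(grid))
  for (j in seq_along(grid)) {
    fit <- onion(ens, delta_t = grid[j], ...)
    ns[j] <- fit$n_states
    e0[j] <- fit$env0_fraction
  }
  out <- data.frame(delta_t_frames = grid, delta_t_time = grid * ens$dt,
                    n_states = ns, env0_fraction = e0)
  class(out) <- c("delta_t_scan", "data.frame")
  attr(out, "dt") <- ens$dt
  out
}

#' @export
print.delta_t_scan <- function(x, ...) {
  cat("delta_t scan (", nrow(x), " resolutions, dt = ",
      attr(x, "dt"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot a time-resolution scan
#'
#' Number of states (left axis, blue) and unclassified ENV0 fraction
#' (right axis, orange) against the time resolution on a log axis.
#'
#' @param x a [delta_t_scan()] result.
#' @param time if `TRUE` the x axis is in time units, else frames.
#' @param ... passed to the base plot call.
#' @export
plot.delta_t_scan <- function(x, time = TRUE, ...) {
  xs <- if (time) x$delta_t_time else x$delta_t_frames
  op <- graphics::par(mar = c(5, 4, 2, 4)); on.exit(graphics::par(op))
  graphics::plot(xs, x$n_states, type = "s", log = "x", col = "blue3",
                 lwd = 2, xlab = if (time) "delta_t (time)" else "delta_t (frames)",
                 ylab = "number of states",
                 ylim = c(0, max(x$n_states) + 0.5), ...)
  graphics::par(new = TRUE)
  graphics::plot(xs, x$env0_fraction, type = "l", log = "x", col = "orange2",
                 lwd = 2, axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4); graphics::mtext("ENV0 fraction", side = 4, line = 2.5)
  invisible(x)
}
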