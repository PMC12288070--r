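#' Information-frustration gap between univariate and combined clusterings
#'
#' Combining two signal dimensions should, ideally, never resolve fewer
#' states than the better of the two alone. In noisy data it can: noise in
#' one dimension degrades states cleanly resolved by the other
#' ("frustrated information"). The gap is quantified per time resolution
#' as `max(n1, n2) - n12`; its positive part is the information lost by
#' combining the dimensions.
#'
#' @param scan1,scan2 [delta_t_scan()] results of the two univariate
#'   signals.
#' @param scan12 [delta_t_scan()] of the combined bivariate signal.
#' @return object of class `frustration_curve`: data.frame with columns
#'   `delta_t_frames`, `delta_t_time`, `n1`, `n2`, `n12`, `gap_raw`,
#'   `info_loss` (= max(gap_raw, 0)).
#' @export
frustration_gap <- function(scan1, scan2, scan12) {
  if (!identical(scan1$delta_t_frames, scan2$delta_t_frames) ||
      !identical(scan1$delta_t_frames, scan12$delta_t_frames))
    stop("the three scans must share one delta_t grid")
  gap <- as.integer(pmax(scan1$n_states, scan2$n_states) - scan12$n_states)
  out <- data.frame(delta_t_frames = scan1$delta_t_frames,
                    delta_t_time = scan1$delta_t_time,
                    n1 = as.integer(scan1$n_states),
                    n2 = as.integer(scan2$n_states),
                    n12 = as.integer(scan12$n_states),
                    gap_raw = gap, info_loss = pmax(gap, 0L))
  class(out) <- c("frustration_curve", "data.frame")
  out
}

#' @export
print.frustration_curve <- function(x, ...) {
  cat(sprintf("frustration curve: info_loss > 0 at %d of %d resolutions (max %d)\n",
              sum(x$info_loss > 0), nrow(x), max(x$info_loss)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.frustration_curve <- function(x, ...) {
  xs <- x$delta_t_time
  graphics::plot(xs, pmax(x$n1, x$n2), type = "s", log = "x", lty = 2,
                 col = "grey40", lwd = 2, xlab = "delta_t (time)",
                 ylab = "number of states",
                 ylim = c(0, max(x$n1, x$n2, x$n12) + 0.5), ...)
  graphics::lines(xs, x$n12, type = "s", col = "blue3", lwd = 2)
  loss <- x$info_loss > 0
  if (any(loss))
    graphics::points(xs[loss], pmax(x$n1, x$n2)[loss], pch = 25,
                     bg = "grey70", col = "grey40")
  graphics::legend("topright", c("best univariate", "combined"),
                   col = c("grey40", "blue3"), lty = c(2, 1), lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Time-resolution windows where at least k states are detected
#'
#' The detection window of a target environment: the maximal intervals of
#' the scanned delta_t grid on which the cluster count reaches `k`.
#' Windows are reported grid-wise (no interpolation between scanned
#' resolutions).
#'
#' @param scan a [delta_t_scan()] result.
#' @param k target state count (>= 1).
#' @return data.frame (class `detection_window`) with one row per maximal
#'   interval: `from_frames`, `to_frames`, `from_time`, `to_time`; zero
#'   rows when `k` states are never detected.
#' @export
detection_window <- function(scan, k) {
  stopifnot(k >= 1)
  hit <- scan$n_states >= k
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  out <- data.frame(from_frames = scan$delta_t_frames[starts[sel]],
                    to_frames = scan$delta_t_frames[ends[sel]],
                    from_time = scan$delta_t_time[starts[sel]],
                    to_time = scan$delta_t_time[ends[sel]])
  class(out) <- c("detection_window", "data.frame")
  attr(out, "k") <- k
  out
}

#' Resample an ensemble or trajectory by an integer stride
#'
#' Keeps frames 1, 1 + stride, 1 + 2*stride, ... and multiplies the
#' sampling interval by the stride, emulating a lower acquisition
#' frequency on the same data.
#'
#' @param x a [signal_ensemble()] or [particle_trajectory()].
#' @param stride integer >= 1, smaller than the frame count.
#' @param ... unused.
#' @return an object of the same class as `x`.
#' @export
resample <- function(x, stride, ...) UseMethod("resample")

check_stride <- function(stride, tt) {
  if (stride < 1 || stride != round(stride)) stop("stride must be a positive integer")
  if (stride >= tt) stop("stride must be smaller than the number of frames")
  as.integer(stride)
}

#' @rdname resample
#' @export
resample.signal_ensemble <- function(x, stride, ...) {
  tt <- dim(x$values)[2]
  stride <- check_stride(stride, tt)
  keep <- seq(1L, tt, by = stride)
  signal_ensemble(x$values[, keep, , drop = FALSE], dt = x$dt * stride)
}

#' @rdname resample
#' @export
resample.particle_trajectory <- function(x, stride, ...) {
  tt <- dim(x$positions)[2]
  stride <- check_stride(stride, tt)
  keep <- seq(1L, tt, by = stride)
  particle_trajectory(x$positions[, keep, , drop = FALSE],
                      if (!is.null(x$velocities))
                        x$velocities[, keep, , drop = FALSE],
                      box = x$box, periodic = x$periodic,
                      dt = x$dt * stride)
}

#' Sampling-frequency scan of a detection window
#'
#' Emulates acquiring the same signal at lower sampling frequencies: for
#' each stride the ensemble is resampled, a full [delta_t_scan()] is run,
#' and the detection window for `k` states is extracted. Windows are
#' reported in absolute time so they are comparable across strides; on
#' clean (denoised) signals the upper window edge -- set by the target
#' state's dwell time -- is expected to be stride-independent, while noisy
#' signals can show spurious stride-dependent detections.
#'
#' @param x ensemble accepted by [onion()].
#' @param strides integer strides to test (e.g. `c(1, 2, 5)`).
#' @param k target state count.
#' @param grid_points nominal per-stride grid size (see [delta_t_grid()]).
#' @param ... passed to [onion()].
#' @return object of class `sampling_scan`: list with one element per
#'   stride, each holding `stride`, `scan` and `window`.
#' @export
sampling_scan <- function(x, strides, k, grid_points = 30L, ...) {
  ens <- as.signal_ensemble(x)
  out <- lapply(strides, function(s) {
    r <- resample(ens, s)
    sc <- delta_t_scan(r, grid = delta_t_grid(dim(r$values)[2], grid_points),
                       ...)
    list(stride = s, scan = sc, window = detection_window(sc, k))
  })
  structure(list(results = out, k = k), class = "sampling_scan")
}

#' @export
print.sampling_scan <- function(x, ...) {
  cat(sprintf("sampling scan: detection windows for >= %d states\n", x$k))
  for (r in x$results) {
    if (nrow(r$window) == 0) {
      cat(sprintf("  stride %d: no detection\n", r$stride))
    } else {
      cat(sprintf("  stride %d: %s\n", r$stride,
                  paste(sprintf("[%g, %g]", r$window$from_time,
                                r$window$to_time), collapse = ", ")))
    }
  }
  invisible(x)
}
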