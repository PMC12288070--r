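#' Particle trajectory container
#'
#' Positions (and optionally velocities) of N particles over T frames in an
#' orthorhombic box with per-axis periodicity. Coordinates are Cartesian with
#' the origin at the box corner, in the trajectory's native length unit
#' (Angstrom for MD-like data, pixels for tracking data). Time is handled in
#' frames internally; `dt` converts to physical time at I/O boundaries only.
#'
#' @param positions N x T x dim numeric array (dim = 2 or 3).
#' @param velocities optional N x T x dim array (length/frame).
#' @param box numeric vector of box edge lengths, one per axis.
#' @param periodic logical vector, one per axis (recycled if length 1).
#' @param dt sampling interval (time per frame).
#' @return object of class `particle_trajectory`.
#' @export
particle_trajectory <- function(positions, velocities = NULL, box,
                                periodic = FALSE, dt = 1) {
  if (!is.array(positions) || length(dim(positions)) != 3L)
    stop("`positions` must be an N x T x dim array")
  ndim <- dim(positions)[3]
  if (!ndim %in% 2:3) stop("spatial dimension must be 2 or 3")
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("positions must be finite")
  if (length(box) != ndim) stop("`box` must have one length per axis")
  if (any(box <= 0)) stop("box dimensions must be positive")
  periodic <- rep_len(as.logical(periodic), ndim)
  if (!is.null(velocities)) {
    if (!identical(dim(velocities), dim(positions)))
      stop("`velocities` must match the shape of `positions`")
  }
  structure(list(positions = positions, velocities = velocities,
                 box = as.numeric(box), periodic = periodic,
                 dt = as.numeric(dt)),
            class = "particle_trajectory")
}

#' @export
print.particle_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("particle_trajectory: %d particles x %d frames, %dD box [%s]%s\n",
              d[1], d[2], d[3], paste(signif(x$box, 4), collapse = " x "),
              if (any(x$periodic)) " (periodic)" else ""))
  if (!is.null(x$velocities)) cat("  with velocities\n")
  cat(sprintf("  dt = %g\n", x$dt))
  invisible(x)
}

#' Minimum-image displacement vectors
#'
#' @param dx matrix of raw displacements (rows = vectors).
#' @param box,periodic box lengths and periodic flags.
#' @return displacement matrix with periodic axes wrapped to [-L/2, L/2).
#' @keywords internal
min_image <- function(dx, box, periodic) {
  for (a in seq_along(box)) {
    if (periodic[a]) dx[, a] <- dx[, a] - box[a] * round(dx[, a] / box[a])
  }
  dx
}

# All pairwise minimum-image distances for one frame (N x dim coords).
pairwise_dist <- function(coords, box, periodic) {
  n <- nrow(coords)
  dmat <- matrix(0, n, n)
  if (n < 2) return(dmat)
  for (i in seq_len(n - 1)) {
    dx <- sweep(coords[(i + 1):n, , drop = FALSE], 2, coords[i, ])
    dx <- min_image(dx, box, periodic)
    dd <- sqrt(rowSums(dx^2))
    dmat[i, (i + 1):n] <- dd
    dmat[(i + 1):n, i] <- dd
  }
  dmat
}

# Neighbor displacement vectors of one center within cutoff (excludes self).
neighbor_vectors <- function(coords, i, cutoff, box, periodic) {
  dx <- sweep(coords[-i, , drop = FALSE], 2, coords[i, ])
  dx <- min_image(dx, box, periodic)
  r <- sqrt(rowSums(dx^2))
  keep <- r <= cutoff
  list(vec = dx[keep, , drop = FALSE], r = r[keep])
}

#' Finite-difference velocities from positions
#'
#' Forward differences (periodic-aware) over `stride` frames, in
#' length/frame of the resulting stride. The last `stride` frames reuse the
#' preceding difference so the shape is preserved.
#'
#' @param traj a `particle_trajectory`.
#' @param stride frame offset for the difference (default 1).
#' @return the trajectory with a `velocities` field filled in.
#' @export
velocities_from_positions <- function(traj, stride = 1L) {
  stopifnot(inherits(traj, "particle_trajectory"), stride >= 1)
  d <- dim(traj$positions)
  n <- d[1]; tt <- d[2]; ndim <- d[3]
  if (stride >= tt) stop("stride must be smaller than the number of frames")
  vel <- array(NA_real_, d)
  for (t in seq_len(tt - stride)) {
    dx <- traj$positions[, t + stride, ] - traj$positions[, t, ]
    dx <- min_image(matrix(dx, nrow = n), traj$box, traj$periodic)
    vel[, t, ] <- dx / stride
  }
  for (t in (tt - stride + 1):tt) vel[, t, ] <- vel[, tt - stride, ]
  traj$velocities <- vel
  traj
}
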