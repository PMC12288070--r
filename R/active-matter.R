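#' Minimum neighbor distance per particle per frame
#'
#' d_min, a proxy for local particle density: for each particle and frame,
#' the (periodic-aware) distance to its closest other particle. Frames with
#' fewer than two particles yield `NA` (the signal is undefined there and
#' is excluded from clustering).
#'
#' @param traj a [particle_trajectory()].
#' @return a [signal_ensemble()] (N x T, univariate).
#' @export
min_neighbor_distance <- function(traj) {
  stopifnot(inherits(traj, "particle_trajectory"))
  d <- dim(traj$positions)
  n <- d[1]; tt <- d[2]
  out <- matrix(NA_real_, n, tt)
  if (n >= 2) {
    for (t in seq_len(tt)) {
      coords <- matrix(traj$positions[, t, ], nrow = n)
      dm <- pairwise_dist(coords, traj$box, traj$periodic)
      diag(dm) <- Inf
      out[, t] <- apply(dm, 1, min)
    }
  }
  signal_ensemble(out, dt = traj$dt)
}

#' Local velocity alignment
#'
#' The polar order parameter phi of each particle: the mean cosine of the
#' angle between its velocity and those of its neighbors within `r_c`,
#'
#'   phi_i = (1 / n_c^i) * sum_j  v_i . v_j / (|v_i| |v_j|),
#'
#' where j runs over the n_c^i neighbors of i (the particle itself is
#' excluded: self-inclusion would bias phi toward +1). phi lies in
#' \[-1, 1\]: +1 for locally coherent motion, ~0 for disordered motion.
#' Particles with no neighbors inside `r_c`, or with zero speed, are
#' undefined (`NA`); zero-speed neighbors are left out of the sum.
#'
#' @param traj a [particle_trajectory()] with velocities (see
#'   [velocities_from_positions()] to derive them from positions).
#' @param r_c neighbor cutoff (length units; e.g. 15 pixels for tracked
#'   colloid data).
#' @return a [signal_ensemble()] (N x T, univariate).
#' @export
local_alignment <- function(traj, r_c) {
  stopifnot(inherits(traj, "particle_trajectory"), r_c > 0)
  if (is.null(traj$velocities))
    stop("trajectory has no velocities; use velocities_from_positions()")
  d <- dim(traj$positions)
  n <- d[1]; tt <- d[2]
  out <- matrix(NA_real_, n, tt)
  for (t in seq_len(tt)) {
    coords <- matrix(traj$positions[, t, ], nrow = n)
    vel <- matrix(traj$velocities[, t, ], nrow = n)
    speed <- sqrt(rowSums(vel^2))
    unit <- vel / ifelse(speed > 0, speed, 1)
    dm <- pairwise_dist(coords, traj$box, traj$periodic)
    cosmat <- unit %*% t(unit)
    for (i in seq_len(n)) {
      if (speed[i] == 0) next
      nb <- which(dm[i, ] <= r_c & seq_len(n) != i & speed > 0)
      if (length(nb) == 0) next
      out[i, t] <- mean(cosmat[i, nb])
    }
  }
  signal_ensemble(out, dt = traj$dt)
}
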