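#' Spatial denoising by neighborhood averaging
#'
#' Replaces each particle's signal (scalar or descriptor vector) at each
#' frame by the unweighted mean over the particle itself and its neighbors
#' within `cutoff` at that frame -- the "_dn" (denoised) variant of a
#' descriptor. Averaging over instantaneous spatial neighborhoods
#' suppresses uncorrelated thermal noise while preserving the slowly
#' varying environment signal; with a cutoff covering the whole
#' (non-periodic) box it degenerates to the frame-wide mean.
#'
#' @param x a [signal_ensemble()] or [descriptor_series()] aligned with
#'   `traj` on (particle, frame).
#' @param traj the [particle_trajectory()] supplying positions.
#' @param cutoff neighbor cutoff (length units); a natural choice for SOAP
#'   descriptors is the SOAP `r_cut` itself.
#' @return an object of the same class as `x`; `descriptor_series` inputs
#'   get provenance `"denoised"`.
#' @export
spatial_average <- function(x, traj, cutoff) {
  stopifnot(inherits(traj, "particle_trajectory"), cutoff > 0)
  is_desc <- inherits(x, "descriptor_series")
  ens <- if (is_desc) x else as.signal_ensemble(x)
  vals <- ens$values
  d <- dim(vals)
  dtraj <- dim(traj$positions)
  if (d[1] != dtraj[1] || d[2] != dtraj[2])
    stop("series and trajectory disagree on (particle, frame) shape")
  n <- d[1]
  out <- vals
  for (t in seq_len(d[2])) {
    coords <- matrix(traj$positions[, t, ], nrow = n)
    adj <- pairwise_dist(coords, traj$box, traj$periodic) <= cutoff
    diag(adj) <- TRUE                      # self always contributes
    deg <- rowSums(adj)
    frame <- matrix(vals[, t, ], nrow = n)
    out[, t, ] <- (adj %*% frame) / deg
  }
  if (is_desc) {
    descriptor_series(out, params = x$params, provenance = "denoised",
                      dt = x$dt)
  } else {
    signal_ensemble(out, dt = ens$dt)
  }
}
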