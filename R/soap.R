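#' SOAP descriptor parameters
#'
#' Parameters of the single-species SOAP (Smooth Overlap of Atomic
#' Positions) power spectrum. The neighbor density around each center is a
#' sum of Gaussians of width `sigma_atom` placed at the neighbors within
#' `r_cut`, tapered smoothly to zero at the cutoff; it is expanded in
#' `n_max` orthonormal radial basis functions times real spherical
#' harmonics up to `l_max`, and summarized rotation-invariantly by the
#' power spectrum p_nn'l.
#'
#' @param r_cut cutoff radius (length units; 10 is a common choice for
#'   water oxygen environments, in Angstrom).
#' @param n_max number of radial basis functions (>= 1).
#' @param l_max maximum angular momentum (>= 0).
#' @param sigma_atom Gaussian smearing width of the neighbor density.
#' @param include_center if `TRUE`, the central particle contributes to its
#'   own density (default `FALSE`: the environment is "all other" particles).
#' @param cutoff_smoothing `"cosine"` (cosine taper over the outer 10% of
#'   `r_cut`, so the descriptor is continuous as neighbors cross the
#'   cutoff) or `"none"` (hard cutoff).
#' @param normalize if `TRUE`, each power-spectrum vector is scaled to unit
#'   Euclidean norm (off by default).
#' @return object of class `soap_params`.
#' @examples
#' p <- soap_params(r_cut = 10, n_max = 8, l_max = 8)
#' soap_n_components(p)  # 576
#' @export
soap_params <- function(r_cut = 10, n_max = 8, l_max = 8, sigma_atom = 0.5,
                        include_center = FALSE,
                        cutoff_smoothing = c("cosine", "none"),
                        normalize = FALSE) {
  cutoff_smoothing <- match.arg(cutoff_smoothing)
  stopifnot(r_cut > 0, n_max >= 1, l_max >= 0, sigma_atom > 0)
  structure(list(r_cut = r_cut, n_max = as.integer(n_max),
                 l_max = as.integer(l_max), sigma_atom = sigma_atom,
                 include_center = include_center,
                 cutoff_smoothing = cutoff_smoothing,
                 normalize = normalize),
            class = "soap_params")
}

#' @export
print.soap_params <- function(x, ...) {
  cat(sprintf(
    "soap_params: r_cut %g, n_max %d, l_max %d (%d components), sigma_atom %g\n",
    x$r_cut, x$n_max, x$l_max, soap_n_components(x), x$sigma_atom))
  invisible(x)
}

#' Number of power-spectrum components
#'
#' `n_max^2 * (l_max + 1)`: all ordered radial pairs (n, n') for each l.
#'
#' @param params a [soap_params()] (or anything with `n_max`, `l_max`).
#' @return integer component count, e.g. 576 for n_max = l_max = 8 and 80
#'   for n_max = l_max = 4.
#' @export
soap_n_components <- function(params) {
  as.integer(params$n_max^2 * (params$l_max + 1))
}

#' Flat component index of (n, n', l) and its inverse
#'
#' The component ordering convention: l varies slowest; within each l block
#' the ordered radial pairs (n, n') are laid out n-major. The flat index is
#' 0-based, i.e. `flat = l * n_max^2 + (n - 1) * n_max + (n' - 1)`, so that
#' component #0 is (1, 1, 0) and, for n_max = 8, component #63 is the
#' all-radial (8, 8, 0) term.
#'
#' @param n,n_prime radial indices in 1..n_max.
#' @param l angular index in 0..l_max.
#' @param params a [soap_params()].
#' @return `soap_component_index`: 0-based flat index (vectorized);
#'   `soap_index_to_nnl`: data.frame with columns n, n_prime, l.
#' @examples
#' p <- soap_params(n_max = 8, l_max = 8)
#' soap_component_index(8, 8, 0, p)   # 63
#' soap_index_to_nnl(63, p)
#' @export
soap_component_index <- function(n, n_prime, l, params) {
  if (any(n < 1 | n > params$n_max) || any(n_prime < 1 | n_prime > params$n_max))
    stop("radial indices must lie in 1..n_max")
  if (any(l < 0 | l > params$l_max))
    stop("angular index must lie in 0..l_max")
  as.integer(l * params$n_max^2 + (n - 1) * params$n_max + (n_prime - 1))
}

#' @rdname soap_component_index
#' @param index 0-based flat index (vectorized).
#' @export
soap_index_to_nnl <- function(index, params) {
  nmax2 <- params$n_max^2
  if (any(index < 0 | index >= nmax2 * (params$l_max + 1)))
    stop("flat index out of range")
  l <- index %/% nmax2
  rest <- index %% nmax2
  data.frame(n = as.integer(rest %/% params$n_max + 1),
             n_prime = as.integer(rest %% params$n_max + 1),
             l = as.integer(l))
}

#' Mask of spherical (l = 0) components
#'
#' Flags the components that encode only radial density: the first
#' n_max^2 entries under the ordering convention. Components with l > 0
#' carry angular (symmetry) information.
#'
#' @param params a [soap_params()].
#' @return logical vector of length [soap_n_components()].
#' @export
soap_spherical_mask <- function(params) {
  soap_index_to_nnl(seq_len(soap_n_components(params)) - 1L, params)$l == 0L
}

# cutoff damping weight for neighbor distances r
cutoff_weight <- function(r, params) {
  w <- as.numeric(r <= params$r_cut)
  if (params$cutoff_smoothing == "cosine") {
    r0 <- 0.9 * params$r_cut
    taper <- r > r0 & r <= params$r_cut
    w[taper] <- 0.5 * (1 + cos(pi * (r[taper] - r0) / (params$r_cut - r0)))
  }
  w
}

#' Density expansion coefficients of one neighborhood
#'
#' Expands the Gaussian-smeared neighbor density around a center in the
#' orthonormal radial basis times real spherical harmonics:
#' c_nlm = sum_j w(r_j) <g_n Y_lm | N(x_j, sigma_atom^2)>. Each neighbor's
#' normalized Gaussian contributes through the standard partial-wave
#' kernel: 4 pi Y_lm(u_j) int r^2 g_n(r) e^{-(r^2+R^2)/(2 s^2)}
#' i_l(r R / s^2) dr, with i_l the modified spherical Bessel function,
#' evaluated in exponentially scaled form for stability. Neighbors beyond
#' `r_cut` are excluded; an empty neighborhood gives all-zero coefficients.
#'
#' @param center length-3 position of the center.
#' @param neighbors matrix of neighbor positions (rows), same frame as the
#'   center; 2D inputs are padded with z = 0.
#' @param params a [soap_params()].
#' @param basis optional precomputed [soap_radial_basis()] (reused across
#'   centers for speed).
#' @return object of class `soap_coefficients`: list `c[[l + 1]]` of
#'   n_max x (2l + 1) matrices (m = -l..l in columns), with `params`
#'   attached.
#' @export
soap_expansion_coefficients <- function(center, neighbors, params,
                                        basis = NULL) {
  if (is.null(basis)) basis <- soap_radial_basis(params)
  if (is.null(neighbors) || length(neighbors) == 0)
    neighbors <- matrix(numeric(0), 0, 3)
  neighbors <- matrix(neighbors, ncol = length(center))
  if (ncol(neighbors) == 2) {
    neighbors <- cbind(neighbors, 0)
    center <- c(center, 0)
  }
  dx <- sweep(neighbors, 2, center)
  r <- sqrt(rowSums(dx^2))
  keep <- r <= params$r_cut
  dx <- dx[keep, , drop = FALSE]; r <- r[keep]
  if (params$include_center) {
    dx <- rbind(dx, c(0, 0, 0)); r <- c(r, 0)
  }
  n_max <- params$n_max; l_max <- params$l_max; s <- params$sigma_atom
  cf <- lapply(0:l_max, function(l) matrix(0, n_max, 2 * l + 1))
  if (length(r) > 0) {
    w <- cutoff_weight(r, params)
    norm_const <- (2 * pi * s^2)^(-3 / 2) * 4 * pi
    rq <- basis$nodes; wq <- basis$weights
    gmat <- basis$evaluate(rq) * (wq * rq^2)   # Q x n_max, weights folded in
    onaxis <- r < 1e-12
    ylm <- real_sph_harm(dx, l_max)            # K x (l_max+1)^2
    for (l in 0:l_max) {
      # radial kernels: K x Q matrix of e^{-(r-R)^2/(2s^2)} * e^{-t} i_l(t)
      kern <- matrix(0, length(r), length(rq))
      for (k in seq_along(r)) {
        if (onaxis[k]) {
          kern[k, ] <- if (l == 0) exp(-rq^2 / (2 * s^2)) else 0
        } else {
          t_arg <- rq * r[k] / s^2
          iexp <- sqrt(pi / (2 * t_arg)) *
            besselI(t_arg, l + 0.5, expon.scaled = TRUE)
          kern[k, ] <- exp(-(rq - r[k])^2 / (2 * s^2)) * iexp
        }
      }
      rad <- kern %*% gmat                      # K x n_max
      cols <- ylm_col(l, -l):ylm_col(l, l)
      cf[[l + 1]] <- norm_const * t(rad) %*% (w * ylm[, cols, drop = FALSE])
    }
  }
  structure(list(c = cf, params = params), class = "soap_coefficients")
}

#' SOAP power spectrum from expansion coefficients
#'
#' p_nn'l = pi * sqrt(8 / (2l + 1)) * sum_m c_nlm c_n'lm, emitted for all
#' n_max^2 ordered (n, n') pairs and flattened with
#' [soap_component_index()]'s convention. The result is invariant under
#' rotation, translation and neighbor permutation, and symmetric in
#' (n, n').
#'
#' @param coeffs a `soap_coefficients` object.
#' @param params a [soap_params()] (defaults to the one on `coeffs`).
#' @return numeric vector of length [soap_n_components()] with a
#'   `components` attribute mapping flat index to (n, n', l).
#' @export
soap_power_spectrum <- function(coeffs, params = coeffs$params) {
  n_max <- params$n_max; l_max <- params$l_max
  out <- numeric(n_max^2 * (l_max + 1))
  for (l in 0:l_max) {
    a <- coeffs$c[[l + 1]]
    p_l <- pi * sqrt(8 / (2 * l + 1)) * (a %*% t(a))
    # t() flattens row-major: within the l block n' varies fastest
    out[l * n_max^2 + seq_len(n_max^2)] <- as.vector(t(p_l))
  }
  if (isTRUE(params$normalize)) {
    nn <- sqrt(sum(out^2))
    if (nn > 0) out <- out / nn
  }
  attr(out, "components") <- soap_index_to_nnl(seq_along(out) - 1L, params)
  out
}

#' Per-particle, per-frame descriptor series
#'
#' A `descriptor_series` holds an N x T x D array of descriptor vectors
#' with component metadata and a provenance tag (`"raw"` or `"denoised"`).
#'
#' @param values N x T x D array.
#' @param params the [soap_params()] (or other parameter object) that
#'   produced the descriptors; may be `NULL` for generic descriptors.
#' @param provenance `"raw"` or `"denoised"`.
#' @param dt sampling interval.
#' @return object of class `descriptor_series`.
#' @export
descriptor_series <- function(values, params = NULL, provenance = "raw",
                              dt = 1) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  structure(list(values = values, params = params, provenance = provenance,
                 dt = dt),
            class = "descriptor_series")
}

#' @export
print.descriptor_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("descriptor_series (%s): %d particles x %d frames x %d components\n",
              x$provenance, d[1], d[2], d[3]))
  invisible(x)
}

#' SOAP power spectra for every particle and frame of a trajectory
#'
#' Runs the neighbor search (minimum-image under the trajectory's periodic
#' flags), density expansion and power spectrum for each particle at each
#' frame. Warns when `r_cut` exceeds half the smallest periodic box length
#' (minimum-image ambiguity).
#'
#' @param traj a [particle_trajectory()] (3D; 2D positions are embedded at
#'   z = 0 in a thin non-periodic slab).
#' @param params a [soap_params()].
#' @return a [descriptor_series()] of shape N x T x
#'   [soap_n_components()], provenance `"raw"`.
#' @examples
#' toy <- gen_two_phase_toy(8, 8, 2, seed = 1)
#' d <- soap_descriptors(toy$traj, soap_params(r_cut = 2, n_max = 2, l_max = 2))
#' dim(d$values)
#' @export
soap_descriptors <- function(traj, params) {
  stopifnot(inherits(traj, "particle_trajectory"),
            inherits(params, "soap_params"))
  d <- dim(traj$positions)
  n <- d[1]; tt <- d[2]; ndim <- d[3]
  per_len <- traj$box[traj$periodic]
  if (length(per_len) && params$r_cut > min(per_len) / 2)
    warning("r_cut exceeds half the smallest periodic box length; ",
            "minimum-image neighborhoods may be truncated")
  basis <- soap_radial_basis(params)
  n_comp <- soap_n_components(params)
  out <- array(NA_real_, c(n, tt, n_comp))
  for (t in seq_len(tt)) {
    coords <- matrix(traj$positions[, t, ], nrow = n)
    for (i in seq_len(n)) {
      nb <- neighbor_vectors(coords, i, params$r_cut, traj$box, traj$periodic)
      vec <- nb$vec
      if (ncol(vec) == 2) vec <- cbind(vec, 0)
      cf <- soap_expansion_coefficients(c(0, 0, 0), vec, params, basis)
      out[i, t, ] <- soap_power_spectrum(cf, params)
    }
  }
  descriptor_series(out, params = params, provenance = "raw", dt = traj$dt)
}
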