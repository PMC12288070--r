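#' Markov-switching Gaussian emission model specification
#'
#' Describes the statistical structure the time-series clustering assumes:
#' each particle's signal is a hidden Markov chain over a few metastable
#' states, with isotropic Gaussian emissions around each state's mean. The
#' mean dwell time of state k is `1 / (1 - transition[k, k])` frames.
#'
#' @param means numeric vector (univariate: one mean per state) or K x d
#'   matrix (d-variate).
#' @param sigmas emission standard deviations: one per state (recycled), or
#'   a K x d matrix for per-dimension noise (e.g. an informative dimension
#'   next to a noisy one). Exact zeros are floored to 1e-9 to avoid
#'   degenerate densities.
#' @param transition K x K row-stochastic matrix of per-frame transition
#'   probabilities.
#' @param initial initial state distribution (default: uniform).
#' @param names optional state labels.
#' @return object of class `markov_spec`.
#' @examples
#' # two states, mean dwell 100 frames each
#' sp <- markov_spec(c(-1, 1), 0.2,
#'                   matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE))
#' @export
markov_spec <- function(means, sigmas, transition, initial = NULL,
                        names = NULL) {
  means <- if (is.matrix(means)) means else matrix(means, ncol = 1)
  k <- nrow(means)
  sigmas <- if (is.matrix(sigmas)) {
    if (!identical(dim(sigmas), dim(means)))
      stop("a sigma matrix must be K x d like `means`")
    sigmas
  } else {
    matrix(rep_len(as.numeric(sigmas), k), k, ncol(means))
  }
  if (any(sigmas < 0)) stop("emission sigma must be >= 0")
  sigmas <- pmax(sigmas, 1e-9)
  transition <- as.matrix(transition)
  if (!identical(dim(transition), c(k, k)))
    stop("transition matrix must be K x K")
  if (any(transition < 0) || any(transition > 1))
    stop("transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  if (is.null(initial)) initial <- rep(1 / k, k)
  if (length(initial) != k || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-12)
    stop("initial distribution must be a length-K probability vector")
  if (is.null(names)) names <- paste0("S", seq_len(k))
  structure(list(means = means, sigmas = sigmas, transition = transition,
                 initial = as.numeric(initial), names = names),
            class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  k <- nrow(x$means)
  dwell <- 1 / pmax(1 - diag(x$transition), 1e-300)
  cat(sprintf("markov_spec: %d states, %d-variate emissions\n", k,
              ncol(x$means)))
  for (i in seq_len(k))
    cat(sprintf("  %s: mean (%s), sigma (%s), mean dwell %.3g frames\n",
                x$names[i], paste(signif(x$means[i, ], 4), collapse = ", "),
                paste(signif(x$sigmas[i, ], 4), collapse = ", "), dwell[i]))
  invisible(x)
}

# One master seed spawns per-purpose substreams so that, e.g., the state
# path stream is unaffected by how many emission draws are consumed.
spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a labelled ensemble of Markov-switching Gaussian signals
#'
#' Simulates `n_series` independent hidden Markov chains from `spec` and
#' emits Gaussian observations around the active state's mean. The returned
#' ground-truth labels make every downstream stage testable without
#' reference data.
#'
#' @param spec a [markov_spec()].
#' @param n_series number of series (particles), >= 1.
#' @param n_frames series length, >= 2.
#' @param seed master seed; the state-path and emission-noise substreams are
#'   derived from it independently.
#' @param dt sampling interval stored on the ensemble.
#' @return list with `ensemble` (a [signal_ensemble()]) and `labels`
#'   (N x T integer matrix of generating states, 1-based).
#' @examples
#' sp <- markov_spec(c(-2, 2), 0.3, diag(2))
#' g <- gen_state_ensemble(sp, n_series = 5, n_frames = 100, seed = 1)
#' table(g$labels[, 1])
#' @export
gen_state_ensemble <- function(spec, n_series, n_frames, seed, dt = 1) {
  stopifnot(inherits(spec, "markov_spec"), n_series >= 1, n_frames >= 2)
  k <- nrow(spec$means); d <- ncol(spec$means)
  seeds <- spawn_seeds(seed, 2)

  # substream 1: state paths
  set.seed(seeds[1])
  labels <- matrix(0L, n_series, n_frames)
  labels[, 1] <- sample.int(k, n_series, replace = TRUE, prob = spec$initial)
  cum <- t(apply(spec$transition, 1, cumsum))
  for (t in 2:n_frames) {
    u <- stats::runif(n_series)
    labels[, t] <- rowSums(u > cum[labels[, t - 1], , drop = FALSE]) + 1L
  }

  # substream 2: emission noise
  set.seed(seeds[2])
  vals <- array(stats::rnorm(n_series * n_frames * d), c(n_series, n_frames, d))
  for (a in seq_len(d)) {
    vals[, , a] <- spec$means[labels, a] + spec$sigmas[labels, a] * vals[, , a]
  }
  list(ensemble = signal_ensemble(vals, dt = dt), labels = labels)
}

#' Two-phase particle toy: lattice slab, liquid region, exchanging interface
#'
#' Emulates solid/liquid phase coexistence: a slab of near-static cubic
#' lattice particles (site + i.i.d. Gaussian jitter), a region of diffusing
#' liquid-like particles (reflected random walk), and an interface layer --
#' particles within one lattice constant of the slab boundary -- whose
#' members stochastically swap behavior each frame. Ground-truth phase
#' labels track the current behavior of every particle.
#'
#' @param n_solid,n_liquid particle counts (>= 0).
#' @param n_frames frames to generate.
#' @param lattice_const lattice constant a (length units).
#' @param jitter_sigma thermal jitter of solid particles about their sites.
#' @param walk_sigma per-frame random-walk step sd of liquid particles.
#' @param exchange_prob per-frame probability that an interface-layer
#'   particle swaps solid <-> liquid behavior.
#' @param seed master seed.
#' @param dt sampling interval.
#' @return list with `traj` (a [particle_trajectory()], periodic in y and z)
#'   and `labels` (N x T integer matrix: 1 = solid, 2 = liquid).
#' @export
gen_two_phase_toy <- function(n_solid, n_liquid, n_frames,
                              lattice_const = 1, jitter_sigma = 0.05,
                              walk_sigma = 0.2, exchange_prob = 0,
                              seed = 1, dt = 1) {
  stopifnot(n_solid >= 0, n_liquid >= 0, n_solid + n_liquid >= 1,
            n_frames >= 1, lattice_const > 0)
  a <- lattice_const
  # lattice slab filling x in [0, nx*a); cross-section sized near-cubic
  side <- max(1L, ceiling(n_solid^(1 / 3)))
  ny <- side; nz <- side
  nx <- max(1L, ceiling(n_solid / (ny * nz)))
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny), iz = seq_len(nz))
  grid <- grid[order(grid$ix, grid$iy, grid$iz), ][seq_len(max(n_solid, 1L)), ]
  sites <- as.matrix(grid - 0.5) * a
  x_slab <- nx * a
  # liquid region sized to ~90% of the solid number density
  vol_liq <- if (n_liquid > 0) n_liquid * a^3 / 0.9 else (ny * nz * a^2) * a
  x_liq <- vol_liq / (ny * a * nz * a)
  box <- c(x_slab + x_liq, ny * a, nz * a)
  if (any(box <= 0)) stop("box dimensions must be positive")

  n <- n_solid + n_liquid
  seeds <- spawn_seeds(seed, 3)
  pos <- array(NA_real_, c(n, n_frames, 3))
  labels <- matrix(0L, n, n_frames)
  phase <- rep(c(1L, 2L), c(n_solid, n_liquid))
  home <- matrix(NA_real_, n, 3)
  if (n_solid > 0) home[seq_len(n_solid), ] <- sites[seq_len(n_solid), , drop = FALSE]

  set.seed(seeds[1])  # liquid initial positions + walk
  cur <- matrix(NA_real_, n, 3)
  if (n_solid > 0) cur[seq_len(n_solid), ] <- home[seq_len(n_solid), ]
  if (n_liquid > 0) {
    cur[n_solid + seq_len(n_liquid), ] <-
      cbind(stats::runif(n_liquid, x_slab, box[1]),
            stats::runif(n_liquid, 0, box[2]),
            stats::runif(n_liquid, 0, box[3]))
  }
  walk_steps <- array(stats::rnorm(n * n_frames * 3, sd = max(walk_sigma, 0)),
                      c(n, n_frames, 3))
  set.seed(seeds[2])  # solid jitter
  jit <- array(stats::rnorm(n * n_frames * 3, sd = max(jitter_sigma, 0)),
               c(n, n_frames, 3))
  set.seed(seeds[3])  # interface exchange
  flips <- matrix(stats::runif(n * n_frames), n, n_frames)

  reflect <- function(z, lo, hi) {
    # reflect a coordinate into [lo, hi]
    w <- hi - lo
    z <- (z - lo) %% (2 * w)
    lo + ifelse(z > w, 2 * w - z, z)
  }
  near_boundary <- function(p) abs(p[, 1] - x_slab) <= a

  for (t in seq_len(n_frames)) {
    solid <- phase == 1L
    if (any(solid)) {
      # liquid->solid converts anchor where the particle froze
      miss <- solid & is.na(home[, 1])
      if (any(miss)) home[miss, ] <- cur[miss, , drop = FALSE]
      cur[solid, ] <- home[solid, , drop = FALSE] + jit[solid, t, ]
    }
    if (any(!solid)) {
      liq <- which(!solid)
      if (t > 1) {
        cur[liq, ] <- cur[liq, , drop = FALSE] + walk_steps[liq, t, ]
        cur[liq, 1] <- reflect(cur[liq, 1], 0, box[1])
        cur[liq, 2] <- cur[liq, 2] %% box[2]
        cur[liq, 3] <- cur[liq, 3] %% box[3]
      }
    }
    labels[, t] <- phase
    pos[, t, ] <- cur
    if (exchange_prob > 0 && t < n_frames) {
      iface <- near_boundary(cur)
      swap <- iface & flips[, t] < exchange_prob
      if (any(swap)) {
        newly_liquid <- swap & phase == 1L
        phase[swap] <- 3L - phase[swap]
        home[newly_liquid, ] <- NA_real_
      }
    }
  }
  traj <- particle_trajectory(pos, box = box,
                              periodic = c(FALSE, TRUE, TRUE), dt = dt)
  list(traj = traj, labels = labels)
}

#' Coherent-wave particle toy (driven-colloid analogue)
#'
#' A 2D field of particles traversed by a band of coherent motion: particles
#' inside a moving band of width `band_width` get velocity
#' `(v_coherent, 0)` plus isotropic jitter, particles outside get jitter
#' only. The band advances along +x by `wave_speed` per frame and wraps
#' periodically. Particle positions stay fixed (the wave travels through the
#' field, as in a velocity wave propagating through a dense colloid layer),
#' so band membership is a purely geometric sweep.
#'
#' @param n_particles particle count.
#' @param box 2-vector of box lengths.
#' @param band_width width of the coherent band along x (< box[1]).
#' @param wave_speed band advance per frame (length/frame).
#' @param v_coherent coherent speed along +x inside the band.
#' @param v_jitter sd of the isotropic velocity jitter.
#' @param n_frames frames.
#' @param seed master seed.
#' @param dt sampling interval.
#' @return list with `traj` (2D [particle_trajectory()] with velocities,
#'   fully periodic) and `labels` (N x T logical matrix, TRUE = in band).
#' @export
gen_wave_toy <- function(n_particles, box = c(100, 100), band_width = 20,
                         wave_speed = 2, v_coherent = 1, v_jitter = 0.1,
                         n_frames = 100, seed = 1, dt = 1) {
  stopifnot(n_particles >= 1, length(box) == 2, band_width > 0,
            band_width < box[1], n_frames >= 1)
  seeds <- spawn_seeds(seed, 2)
  set.seed(seeds[1])
  cur <- cbind(stats::runif(n_particles, 0, box[1]),
               stats::runif(n_particles, 0, box[2]))
  set.seed(seeds[2])
  jit <- array(stats::rnorm(n_particles * n_frames * 2, sd = max(v_jitter, 0)),
               c(n_particles, n_frames, 2))
  pos <- array(NA_real_, c(n_particles, n_frames, 2))
  vel <- array(NA_real_, c(n_particles, n_frames, 2))
  labels <- matrix(FALSE, n_particles, n_frames)
  for (t in seq_len(n_frames)) {
    x0 <- ((t - 1) * wave_speed) %% box[1]
    dx <- (cur[, 1] - x0) %% box[1]
    inband <- dx < band_width
    v <- jit[, t, ]
    v[inband, 1] <- v[inband, 1] + v_coherent
    pos[, t, ] <- cur
    vel[, t, ] <- v
    labels[, t] <- inband
  }
  traj <- particle_trajectory(pos, vel, box = box, periodic = TRUE, dt = dt)
  list(traj = traj, labels = labels)
}
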