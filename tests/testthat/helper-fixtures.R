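# Shared fixtures: every input is generated in code at test time.

# three metastable states: outer dwells 1000 frames, middle dwell 50
three_state_transition <- function() {
  matrix(c(0.999, 0.001, 0,
           0.01,  0.98,  0.01,
           0,     0.001, 0.999), 3, 3, byrow = TRUE)
}

three_state_spec <- function(sigma = 0.25) {
  markov_spec(c(-2, 0, 2), sigma, three_state_transition())
}

# bivariate frustration fixture: dim 1 resolves three states; dim 2 carries
# only the two dominant states, drowned in noise with sigma twice the
# minor state's separation (2) from its neighbors in dim 1
frustration_spec <- function() {
  markov_spec(cbind(c(-2, 0, 2), c(-2, -2, 2)),
              cbind(rep(0.25, 3), rep(4, 3)),
              three_state_transition())
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

random_neighborhood <- function(n = 8, scale = 1.5) {
  matrix(stats::rnorm(n * 3, sd = scale), ncol = 3)
}

# independent oracle for the density expansion coefficients: direct 3D
# spherical-grid quadrature of <g_n Y_lm | density>, with Y_lm rebuilt from
# pracma::legendre (not the package's own harmonics)
oracle_coefficients <- function(neighbors, params, nr = 90, nth = 60,
                                nph = 72) {
  basis <- dynenv:::soap_radial_basis(params)
  glr <- pracma::gaussLegendre(nr, 0, basis$r_max)
  glt <- pracma::gaussLegendre(nth, -1, 1)
  ph <- (seq_len(nph) - 1) * 2 * pi / nph
  s <- params$sigma_atom
  r <- matrix(neighbors, ncol = 3)
  bigr <- sqrt(rowSums(r^2))
  keep <- bigr <= params$r_cut
  r <- r[keep, , drop = FALSE]; bigr <- bigr[keep]
  w <- dynenv:::cutoff_weight(bigr, params)
  grid <- expand.grid(ir = seq_len(nr), it = seq_len(nth), ip = seq_len(nph))
  rr <- glr$x[grid$ir]; ct <- glt$x[grid$it]
  st <- sqrt(1 - ct^2); pp <- ph[grid$ip]
  gx <- rr * st * cos(pp); gy <- rr * st * sin(pp); gz <- rr * ct
  wt <- glr$w[grid$ir] * rr^2 * glt$w[grid$it] * (2 * pi / nph)
  rho <- numeric(length(rr))
  for (j in seq_len(nrow(r))) {
    d2 <- (gx - r[j, 1])^2 + (gy - r[j, 2])^2 + (gz - r[j, 3])^2
    rho <- rho + w[j] * (2 * pi * s^2)^(-1.5) * exp(-d2 / (2 * s^2))
  }
  gmat <- basis$evaluate(rr)
  out <- vector("list", params$l_max + 1)
  for (l in 0:params$l_max) {
    p <- pracma::legendre(l, ct)
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    ylm <- matrix(0, length(rr), 2 * l + 1)
    for (m in 0:l) {
      nc <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      if (m == 0) {
        ylm[, l + 1] <- nc * p[1, ]
      } else {
        ylm[, l + 1 + m] <- sqrt(2) * nc * p[m + 1, ] * cos(m * pp)
        ylm[, l + 1 - m] <- sqrt(2) * nc * p[m + 1, ] * sin(m * pp)
      }
    }
    cl <- matrix(0, params$n_max, 2 * l + 1)
    for (n in seq_len(params$n_max))
      cl[n, ] <- colSums(wt * rho * gmat[, n] * ylm)
    out[[l + 1]] <- cl
  }
  out
}

max_rel_diff <- function(a, b) {
  s <- max(abs(a), abs(b))
  if (s == 0) return(0)
  max(abs(a - b)) / s
}
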