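# Real spherical harmonics and the orthonormal Gaussian radial basis used by
# the SOAP descriptor. All arithmetic is real; the Condon-Shortley phase is
# included in the associated Legendre recursion (it cancels in any power
# spectrum but matters when comparing coefficients across implementations).

#' Real spherical harmonics up to l_max
#'
#' Evaluates all real spherical harmonics Y_lm, l = 0..l_max, m = -l..l, at
#' a set of unit vectors, using the stable normalized associated-Legendre
#' recursion. Convention: m > 0 pairs with cos(m phi), m < 0 with
#' sin(|m| phi), both carrying sqrt(2); Y_00 = 1/sqrt(4 pi).
#'
#' @param u n x 3 matrix of unit vectors (rows need not be exactly unit
#'   norm; they are normalized).
#' @param l_max maximum angular momentum (>= 0).
#' @return n x (l_max + 1)^2 matrix; column order l = 0, 1, ... with
#'   m = -l..l inside each l block.
#' @keywords internal
real_sph_harm <- function(u, l_max) {
  u <- matrix(u, ncol = 3)
  nr <- sqrt(rowSums(u^2))
  nr[nr == 0] <- 1
  u <- u / nr
  n <- nrow(u)
  ct <- pmin(pmax(u[, 3], -1), 1)          # cos(theta)
  st <- sqrt(pmax(0, 1 - ct^2))            # sin(theta) >= 0
  phi <- atan2(u[, 2], u[, 1])

  # Pbar[l][m]: normalized associated Legendre, Y_l0 = Pbar_l0
  pbar <- vector("list", l_max + 1)
  for (l in 0:l_max) pbar[[l + 1]] <- matrix(0, n, l + 1)
  pbar[[1]][, 1] <- sqrt(1 / (4 * pi))
  if (l_max >= 1) {
    for (m in 1:l_max) {   # diagonal Pbar_m^m
      pbar[[m + 1]][, m + 1] <-
        -sqrt((2 * m + 1) / (2 * m)) * st * pbar[[m]][, m]
    }
    for (m in 0:(l_max - 1)) {  # Pbar_{m+1}^m
      pbar[[m + 2]][, m + 1] <- sqrt(2 * m + 3) * ct * pbar[[m + 1]][, m + 1]
    }
    if (l_max >= 2) {
      for (l in 2:l_max) {
        ms <- 0:(l - 2)
        a <- sqrt((4 * l^2 - 1) / (l^2 - ms^2))
        b <- sqrt(((l - 1)^2 - ms^2) / (4 * (l - 1)^2 - 1))
        for (m in ms) {
          pbar[[l + 1]][, m + 1] <-
            a[m + 1] * (ct * pbar[[l]][, m + 1] -
                        b[m + 1] * pbar[[l - 1]][, m + 1])
        }
      }
    }
  }

  out <- matrix(0, n, (l_max + 1)^2)
  col <- 1L
  s2 <- sqrt(2)
  for (l in 0:l_max) {
    if (l >= 1) {
      for (m in l:1) {  # m = -l..-1 -> sin components
        out[, col] <- s2 * pbar[[l + 1]][, m + 1] * sin(m * phi)
        col <- col + 1L
      }
    }
    out[, col] <- pbar[[l + 1]][, 1]; col <- col + 1L
    if (l >= 1) {
      for (m in 1:l) {
        out[, col] <- s2 * pbar[[l + 1]][, m + 1] * cos(m * phi)
        col <- col + 1L
      }
    }
  }
  out
}

# Column index of (l, m) in the real_sph_harm layout (1-based).
ylm_col <- function(l, m) l^2 + l + m + 1L

#' Orthonormal Gaussian radial basis
#'
#' The SOAP radial basis: `n_max` Gaussian primitives with centers spaced
#' evenly on [0, r_cut] and width r_cut / n_max, orthonormalized
#' sequentially (Gram-Schmidt via the Cholesky factor of the numerical
#' overlap matrix under the measure r^2 dr on [0, r_max]).
#'
#' @param params a [soap_params()].
#' @param n_quad number of Gauss-Legendre nodes used for the overlap.
#' @return list with `evaluate(r)` returning a length(r) x n_max matrix of
#'   basis values, the quadrature nodes/weights, and `r_max`.
#' @keywords internal
soap_radial_basis <- function(params, n_quad = 120) {
  n_max <- params$n_max
  width <- params$r_cut / n_max
  centers <- if (n_max == 1) params$r_cut / 2
             else seq(0, params$r_cut, length.out = n_max)
  r_max <- params$r_cut + 5 * max(width, params$sigma_atom)
  gl <- pracma::gaussLegendre(n_quad, 0, r_max)
  prim <- function(r) {
    outer(r, centers, function(rr, cc) exp(-(rr - cc)^2 / (2 * width^2)))
  }
  phi <- prim(gl$x)                       # Q x n_max
  s <- t(phi) %*% (gl$w * gl$x^2 * phi)   # overlap under r^2 dr
  w_mat <- solve(t(chol(s)))              # lower-triangular: sequential GS
  list(
    evaluate = function(r) {
      m <- prim(r)
      m %*% t(w_mat)
    },
    nodes = gl$x, weights = gl$w, r_max = r_max, centers = centers,
    width = width
  )
}
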