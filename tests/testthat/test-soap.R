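test_that("component count, index convention and spherical mask agree", {
  p8 <- soap_params(n_max = 8, l_max = 8)
  p4 <- soap_params(n_max = 4, l_max = 4)
  expect_identical(soap_n_components(p8), 576L)
  expect_identical(soap_n_components(p4), 80L)

  expect_identical(soap_component_index(1, 1, 0, p8), 0L)
  expect_identical(soap_component_index(8, 8, 0, p8), 63L)
  expect_error(soap_component_index(9, 1, 0, p8), "1..n_max")
  expect_error(soap_component_index(1, 1, 9, p8), "0..l_max")

  # bijectivity over the whole range
  idx <- 0:(soap_n_components(p8) - 1L)
  nnl <- soap_index_to_nnl(idx, p8)
  expect_identical(soap_component_index(nnl$n, nnl$n_prime, nnl$l, p8), idx)

  m8 <- soap_spherical_mask(p8)
  expect_identical(sum(m8), 64L)
  expect_true(all(which(m8) == 1:64))  # the l = 0 block is 0..63
  expect_identical(sum(soap_spherical_mask(p4)), 16L)
  expect_false(m8[237 + 1])            # component #237 is angular (l > 0)
})

test_that("empty and axially symmetric neighborhoods force zero coefficients", {
  p <- soap_params(r_cut = 4, n_max = 2, l_max = 2, sigma_atom = 0.5)
  cf0 <- soap_expansion_coefficients(c(0, 0, 0), NULL, p)
  expect_true(all(vapply(cf0$c, function(m) all(m == 0), logical(1))))
  expect_true(all(soap_power_spectrum(cf0) == 0))

  # one neighbor on +z: only m = 0 survives
  cfz <- soap_expansion_coefficients(c(0, 0, 0), matrix(c(0, 0, 2), 1), p)
  for (l in 0:2) {
    off_axis <- setdiff(seq_len(2 * l + 1), l + 1)
    if (length(off_axis))
      expect_true(all(abs(cfz$c[[l + 1]][, off_axis]) < 1e-14))
    expect_gt(max(abs(cfz$c[[l + 1]][, l + 1])), 0)
  }
})

test_that("power spectrum equals the explicit-loop evaluation", {
  p <- soap_params(n_max = 2, l_max = 1)
  set.seed(3)
  cf <- structure(list(c = list(matrix(rnorm(2), 2, 1),
                                matrix(rnorm(6), 2, 3)),
                       params = p), class = "soap_coefficients")
  ps <- soap_power_spectrum(cf)
  for (l in 0:1) for (n in 1:2) for (np in 1:2) {
    expected <- 0
    for (m in seq_len(2 * l + 1))
      expected <- expected + cf$c[[l + 1]][n, m] * cf$c[[l + 1]][np, m]
    expected <- pi * sqrt(8 / (2 * l + 1)) * expected
    expect_equal(ps[soap_component_index(n, np, l, p) + 1], expected,
                 tolerance = 1e-12)
  }
  # symmetry p_nn'l = p_n'nl holds exactly
  idx <- soap_index_to_nnl(seq_along(ps) - 1L, p)
  expect_identical(ps[soap_component_index(idx$n, idx$n_prime, idx$l, p) + 1],
                   ps[soap_component_index(idx$n_prime, idx$n, idx$l, p) + 1])
})

test_that("coefficients match the 3D quadrature oracle", {
  p <- soap_params(r_cut = 4, n_max = 2, l_max = 2, sigma_atom = 0.5)
  # single neighbor at r = 2 plus a 3-neighbor configuration
  for (nb in list(matrix(c(0.8, -1.2, 1.1), 1),
                  matrix(c(0, 0, 2,
                           1.1, -0.4, 0.8,
                           -0.9, 1.5, -0.3), ncol = 3, byrow = TRUE))) {
    cf <- soap_expansion_coefficients(c(0, 0, 0), nb, p)
    oc <- oracle_coefficients(nb, p)
    for (l in 0:2)
      expect_lt(max_rel_diff(cf$c[[l + 1]], oc[[l + 1]]), 1e-6)
  }
})

test_that("spectra are invariant under rotation, translation, permutation", {
  set.seed(21)
  p <- soap_params(r_cut = 5, n_max = 4, l_max = 4, sigma_atom = 0.5)
  for (rep in 1:12) {
    nb <- random_neighborhood(n = sample(2:9, 1))
    ps <- soap_power_spectrum(soap_expansion_coefficients(c(0, 0, 0), nb, p))
    r <- random_rotation()
    ps_rot <- soap_power_spectrum(
      soap_expansion_coefficients(c(0, 0, 0), nb %*% t(r), p))
    expect_lt(max_rel_diff(ps, ps_rot), 1e-8)
    sh <- rnorm(3, sd = 4)
    ps_tr <- soap_power_spectrum(
      soap_expansion_coefficients(sh, sweep(nb, 2, -sh), p))
    expect_lt(max_rel_diff(ps, ps_tr), 1e-12)
    ps_pm <- soap_power_spectrum(
      soap_expansion_coefficients(c(0, 0, 0), nb[sample(nrow(nb)), ], p))
    expect_lt(max_rel_diff(ps, ps_pm), 1e-12)
  }
})

test_that("coefficients are additive over neighbor subsets", {
  p <- soap_params(r_cut = 5, n_max = 3, l_max = 3)
  set.seed(5)
  a <- random_neighborhood(4); b <- random_neighborhood(3)
  cf_a <- soap_expansion_coefficients(c(0, 0, 0), a, p)
  cf_b <- soap_expansion_coefficients(c(0, 0, 0), b, p)
  cf_ab <- soap_expansion_coefficients(c(0, 0, 0), rbind(a, b), p)
  for (l in 0:3)
    expect_equal(cf_ab$c[[l + 1]], cf_a$c[[l + 1]] + cf_b$c[[l + 1]],
                 tolerance = 1e-12)
})

test_that("descriptor_series has the right shape and time behavior", {
  p <- soap_params(r_cut = 2, n_max = 4, l_max = 4, sigma_atom = 0.4)
  toy <- gen_two_phase_toy(8, 2, 3, jitter_sigma = 0, walk_sigma = 0,
                           seed = 1)
  # box is deliberately small; the half-box warning has its own test below
  d <- suppressWarnings(soap_descriptors(toy$traj, p))
  expect_identical(dim(d$values), c(10L, 3L, 80L))
  expect_identical(d$provenance, "raw")
  # frozen configuration: descriptors constant along time
  expect_equal(d$values[, 2, ], d$values[, 1, ], tolerance = 1e-12)
  expect_equal(d$values[, 3, ], d$values[, 1, ], tolerance = 1e-12)
})

test_that("rigid rotation of a configuration leaves descriptors unchanged", {
  set.seed(8)
  coords <- matrix(runif(7 * 3, 2, 8), ncol = 3)
  r <- random_rotation()
  center_pt <- colMeans(coords)
  rot <- sweep(sweep(coords, 2, center_pt) %*% t(r), 2, -center_pt)
  pos <- array(NA_real_, c(7, 2, 3))
  pos[, 1, ] <- coords; pos[, 2, ] <- rot
  traj <- particle_trajectory(pos, box = c(20, 20, 20), periodic = FALSE)
  d <- soap_descriptors(traj, soap_params(r_cut = 4, n_max = 3, l_max = 3))
  expect_lt(max_rel_diff(d$values[, 1, ], d$values[, 2, ]), 1e-8)
})

test_that("own spherical harmonics agree with the pracma construction", {
  set.seed(13)
  u <- matrix(rnorm(30), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  mine <- dynenv:::real_sph_harm(u, 4)
  ct <- u[, 3]; pp <- atan2(u[, 2], u[, 1])
  for (l in 0:4) {
    p <- pracma::legendre(l, ct)
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    for (m in 0:l) {
      nc <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      ref <- if (m == 0) nc * p[1, ] else sqrt(2) * nc * p[m + 1, ] * cos(m * pp)
      expect_equal(mine[, dynenv:::ylm_col(l, m)], ref, tolerance = 1e-12)
      if (m > 0)
        expect_equal(mine[, dynenv:::ylm_col(l, -m)],
                     sqrt(2) * nc * p[m + 1, ] * sin(m * pp), tolerance = 1e-12)
    }
  }
})

test_that("r_cut beyond half the periodic box warns but still runs", {
  toy <- gen_two_phase_toy(8, 2, 1, seed = 1)
  p <- soap_params(r_cut = max(toy$traj$box), n_max = 2, l_max = 1)
  expect_warning(soap_descriptors(toy$traj, p), "minimum-image")
})
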