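test_that("markov_spec validates its inputs", {
  expect_error(markov_spec(c(0, 1), 0.1, matrix(c(0.9, 0.2, 0.2, 0.9), 2)),
               "sum to 1")
  expect_error(markov_spec(c(0, 1), -0.1, diag(2)), "sigma")
  expect_error(markov_spec(c(0, 1), 0.1, diag(2), initial = c(0.7, 0.7)),
               "probability")
  # zero sigma is floored, not rejected
  sp <- markov_spec(0, 0, matrix(1))
  expect_gt(sp$sigmas[1, 1], 0)
})

test_that("degenerate emission and absorbing dynamics behave as forced", {
  g <- gen_state_ensemble(markov_spec(0, 0, matrix(1)), 5, 50, seed = 1)
  expect_true(all(abs(g$ensemble$values) < 1e-6))
  expect_true(all(g$labels == 1L))

  sp <- markov_spec(c(-1, 1), 0.1, diag(2), initial = c(0.5, 0.5))
  g2 <- gen_state_ensemble(sp, 20, 100, seed = 2)
  expect_true(all(g2$labels == g2$labels[, 1]))
})

test_that("identical seeds give bit-identical ensembles", {
  sp <- three_state_spec()
  a <- gen_state_ensemble(sp, 10, 200, seed = 7)
  b <- gen_state_ensemble(sp, 10, 200, seed = 7)
  expect_identical(a$ensemble$values, b$ensemble$values)
  expect_identical(a$labels, b$labels)
  c <- gen_state_ensemble(sp, 10, 200, seed = 8)
  expect_false(identical(a$labels, c$labels))
})

test_that("empirical dwell times match the transition matrix", {
  # symmetric telegraph, switch probability 0.01 -> mean dwell 100 frames;
  # oracle: mean geometric sojourn length counted on the generated labels
  sp <- markov_spec(c(0, 5), 0.1,
                    matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE))
  g <- gen_state_ensemble(sp, 500, 5000, seed = 11)
  sojourns <- unlist(apply(g$labels, 1, function(z) rle(z)$lengths))
  # interior sojourns only (first/last are censored)
  interior <- unlist(apply(g$labels, 1, function(z) {
    r <- rle(z)$lengths
    if (length(r) > 2) r[2:(length(r) - 1)] else numeric(0)
  }))
  expect_gt(length(interior), 1000)
  expect_lt(abs(mean(interior) - 100) / 100, 0.05)
})

test_that("emission means and occupancies match ground truth", {
  sp <- three_state_spec()
  g <- gen_state_ensemble(sp, 100, 2000, seed = 3)
  v <- g$ensemble$values[, , 1]
  for (k in 1:3) {
    n_k <- sum(g$labels == k)
    se <- 0.25 / sqrt(n_k)
    expect_lt(abs(mean(v[g$labels == k]) - sp$means[k, 1]), 3 * se)
  }
  # stationary distribution of the chain vs empirical occupancy
  ev <- eigen(t(sp$transition))
  pi_st <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_st <- pi_st / sum(pi_st)
  occ <- tabulate(g$labels, 3) / length(g$labels)
  # 3 binomial SEs, ignoring autocorrelation would be too tight: use the
  # dwell-inflated effective sample size (n series * expected switches)
  n_eff <- 100 * (2000 / 1000)
  for (k in 1:3)
    expect_lt(abs(occ[k] - pi_st[k]), 3 * sqrt(pi_st[k] * (1 - pi_st[k]) / n_eff))
})

test_that("two-phase toy: frozen lattice, label constancy, densities", {
  frozen <- gen_two_phase_toy(27, 10, 5, jitter_sigma = 0, exchange_prob = 0,
                              seed = 1)
  solid <- frozen$traj$positions[1:27, , ]
  for (t in 2:5) expect_identical(solid[, t, ], solid[, 1, ])
  expect_true(all(frozen$labels == frozen$labels[, 1]))

  # neighbor counts from the distance matrix equal a plain double loop
  toy <- gen_two_phase_toy(64, 40, 3, lattice_const = 1, jitter_sigma = 0.02,
                           walk_sigma = 0.1, seed = 2)
  coords <- matrix(toy$traj$positions[, 1, ], ncol = 3)
  dm <- dynenv:::pairwise_dist(coords, toy$traj$box, toy$traj$periodic)
  counts <- rowSums(dm <= 1.2 & dm > 0)
  brute <- integer(104)
  for (i in 1:104) for (j in 1:104) {
    if (i == j) next
    dx <- coords[i, ] - coords[j, ]
    for (a in 2:3) dx[a] <- dx[a] - toy$traj$box[a] * round(dx[a] / toy$traj$box[a])
    if (sqrt(sum(dx^2)) <= 1.2) brute[i] <- brute[i] + 1L
  }
  expect_identical(as.integer(counts), brute)
  # lattice particles sit ~one lattice constant apart; the liquid is looser
  dmin <- min_neighbor_distance(toy$traj)$values[, 1, 1]
  lab1 <- toy$labels[, 1]
  expect_gt(mean(dmin[lab1 == 1]), mean(dmin[lab1 == 2]))
})

test_that("two-phase exchange stays confined to the interface layer", {
  toy <- gen_two_phase_toy(64, 40, 50, exchange_prob = 0.2, seed = 4)
  flips <- which(toy$labels[, -1] != toy$labels[, -50], arr.ind = TRUE)
  expect_gt(nrow(flips), 0)
  a <- 1
  x_slab <- ceiling(64 / 16) * a  # nx * lattice_const for 64 = 4x4x4
  for (r in seq_len(nrow(flips))) {
    x <- toy$traj$positions[flips[r, 1], flips[r, 2], 1]
    expect_lt(abs(x - x_slab), a + 1e-9)
  }
})

test_that("wave toy velocities and band sweep match the geometry", {
  w <- gen_wave_toy(50, box = c(60, 40), band_width = 12, wave_speed = 2,
                    v_coherent = 1, v_jitter = 0, n_frames = 60, seed = 1)
  inb <- w$labels
  v <- w$traj$velocities
  expect_true(all(abs(v[, , 1][inb] - 1) < 1e-12))
  expect_true(all(abs(v[, , 2][inb]) < 1e-12))
  expect_true(all(abs(v[, , 1][!inb]) < 1e-12))

  # static band: membership never changes
  w0 <- gen_wave_toy(30, box = c(60, 40), band_width = 12, wave_speed = 0,
                     v_coherent = 1, v_jitter = 0.1, n_frames = 20, seed = 2)
  expect_true(all(w0$labels == w0$labels[, 1]))

  # fraction of frames in-band ~ band_width / box_x (geometric sweep oracle):
  # over one full period of 30 frames the band covers each particle for
  # band_width / wave_speed = 6 frames
  period <- 60 / 2
  frames_in <- rowSums(w$labels[, 1:period])
  expect_true(all(abs(frames_in - 12 / 2) <= 2))
})
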