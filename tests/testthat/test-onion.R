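test_that("input validation", {
  x <- signal_ensemble(matrix(rnorm(100), 10, 10))
  expect_error(onion(x, delta_t = 1), ">= 2")
  expect_error(onion(x, delta_t = 11), "exceeds")
  expect_error(onion(x, delta_t = 5, min_population = 0), "min_population")
  expect_error(onion(signal_ensemble(matrix(NA_real_, 2, 5)), 2), "empty")
})

test_that("a single Gaussian state is recovered with little ENV0", {
  g <- gen_state_ensemble(markov_spec(0, 0.2, matrix(1)), 200, 1000, seed = 1)
  f <- onion(g$ensemble, delta_t = 10)
  expect_identical(f$n_states, 1L)
  se <- 0.2 / sqrt(sum(f$labels == 1))
  expect_lt(abs(coef(f)[[1]]), 3 * se + 1e-3)
  expect_lte(f$env0_fraction, 0.05)
})

test_that("two static well-separated groups are both recovered", {
  sp <- markov_spec(c(0, 5), 0.1, diag(2))
  g <- gen_state_ensemble(sp, 200, 1000, seed = 2)
  f <- onion(g$ensemble, delta_t = 10)
  expect_identical(f$n_states, 2L)
  m <- sort(coef(f))
  pops <- sapply(f$states, `[[`, "population")
  se <- 0.1 / sqrt(pops * 200 * 1000)
  expect_lt(abs(m[1] - 0), 3 * se[1] + 1e-3)
  expect_lt(abs(m[2] - 5), 3 * se[2] + 1e-3)
  expect_lte(f$env0_fraction, 0.01)
  # labels agree with ground truth up to state numbering
  agreement <- mean((f$labels == g$labels)[f$labels > 0])
  expect_gt(agreement, 0.99)
})

test_that("the 1% population rule dissolves a minority state into ENV0", {
  maj <- gen_state_ensemble(markov_spec(0, 0.1, matrix(1)), 399, 500, seed = 4)
  mnr <- gen_state_ensemble(markov_spec(5, 0.1, matrix(1)), 1, 500, seed = 5)
  vals <- rbind(maj$ensemble$values[, , 1], mnr$ensemble$values[, , 1])
  f <- onion(signal_ensemble(vals), delta_t = 10)
  expect_identical(f$n_states, 1L)
  expect_true(all(f$labels[400, ] == 0L))   # the 0.25% series is ENV0
})

test_that("time resolution trades off detection of the short-lived state", {
  g <- gen_state_ensemble(three_state_spec(), 200, 5000, seed = 3)
  f10 <- onion(g$ensemble, delta_t = 10)
  expect_identical(f10$n_states, 3L)
  f200 <- onion(g$ensemble, delta_t = 200)
  expect_lte(f200$n_states, 2L)
})

test_that("label runs respect delta_t and populations add up", {
  g <- gen_state_ensemble(three_state_spec(), 50, 800, seed = 6)
  for (dt in c(5, 40)) {
    f <- onion(g$ensemble, delta_t = dt)
    for (i in seq_len(nrow(f$labels))) {
      r <- rle(f$labels[i, ])
      expect_true(all(r$lengths[r$values > 0] >= dt))
    }
    pops <- sum(sapply(f$states, `[[`, "population"))
    expect_equal(pops + f$env0_fraction, 1, tolerance = 1e-12)
  }
})

test_that("missing values break runs and stay unclassified", {
  g <- gen_state_ensemble(markov_spec(0, 0.1, matrix(1)), 30, 200, seed = 7)
  v <- g$ensemble$values
  v[1, 50:60, 1] <- NA
  f <- onion(signal_ensemble(v), delta_t = 10)
  expect_true(all(f$labels[1, 50:60] == 0L))
  expect_identical(f$n_states, 1L)
})

test_that("well-separated states are recovered across seeds", {
  # separation 6 sigma, dwells >= 4 delta_t
  sp <- markov_spec(c(0, 3), 0.5,
                    matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE))
  hits <- 0L
  for (s in 1:20) {
    g <- gen_state_ensemble(sp, 40, 600, seed = 200 + s)
    f <- onion(g$ensemble, delta_t = 20)
    if (f$n_states == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("at delta_t = T a multi-transition series is ENV0 or single-labelled", {
  sp <- markov_spec(c(-1, 1), 0.05,
                    matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE))
  g <- gen_state_ensemble(sp, 50, 300, seed = 8)
  f <- onion(g$ensemble, delta_t = 300)
  for (i in 1:50) {
    lab <- unique(f$labels[i, ])
    expect_true(identical(lab, 0L) || length(lab) == 1L)
    if (length(unique(g$labels[i, ])) > 1) expect_identical(unique(f$labels[i, ]), 0L)
  }
})

test_that("bivariate clustering recovers two well-separated 2D states", {
  sp <- markov_spec(cbind(c(0, 3), c(0, -3)), 0.3,
                    matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE))
  g <- gen_state_ensemble(sp, 60, 800, seed = 9)
  f <- onion(g$ensemble, delta_t = 10)
  expect_identical(f$n_states, 2L)
  m <- coef(f)
  expect_equal(unname(m[order(m[, 1]), ]), cbind(c(0, 3), c(0, -3)),
               tolerance = 0.1)
  # predict() re-applies the refined states: labels agree on essentially
  # all points (boundary points may differ after refinement)
  pred <- predict(f, g$ensemble)
  both <- pred > 0L & f$labels > 0L
  expect_gt(mean(pred[both] == f$labels[both]), 0.999)
  expect_gt(mean(pred == f$labels), 0.95)
  expect_identical(sort(unique(as.vector(pred))), c(0L, 1L, 2L))
})

test_that("print, summary, coef and plot methods work", {
  g <- gen_state_ensemble(markov_spec(c(0, 4), 0.2, diag(2)), 30, 200,
                          seed = 10)
  f <- onion(g$ensemble, delta_t = 5)
  expect_output(print(f), "2 states")
  s <- summary(f)
  expect_s3_class(s, "summary.onion")
  expect_identical(nrow(s$states), 2L)
  expect_length(coef(f), 2L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
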