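#' Onion clustering of single-particle time series
#'
#' Iterative Gaussian-peeling clustering of an ensemble of per-particle
#' signals at a fixed time resolution `delta_t`. At each iteration the
#' probability density of the still-unassigned points is estimated; a
#' Gaussian is fitted to its highest peak (between the flanking local
#' minima); every maximal contiguous run of at least `delta_t` frames
#' whose values all lie within `k_sigma` spreads of the state mean
#' (Mahalanobis distance at most `k_sigma` in the multivariate case) is
#' assigned to that state; assigned points are removed and the density
#' re-estimated. Peeling stops when no new state gains at least
#' `min_population` of all points. States ending below `min_population`
#' are dissolved and their points left unclassified. Unclassified points
#' -- signal stretches that never dwell in any state for `delta_t` frames,
#' and missing values -- form the ENV0 cluster, labelled 0.
#'
#' `delta_t` is the single resolution parameter: the minimum time a signal
#' must stay in a state to be classified there. Small `delta_t` resolves
#' short-lived environments at the cost of noise sensitivity; large
#' `delta_t` keeps only long-lived states. Scan it with [delta_t_scan()].
#'
#' @param x a [signal_ensemble()] (N x T, univariate, or N x T x d),
#'   matrix, or 3D array. Missing values break runs and count toward ENV0.
#' @param delta_t time resolution in frames (>= 2, <= T).
#' @param k_sigma assignment half-width in state spreads (default 3: wide
#'   enough that genuinely in-state Gaussian excursions rarely break a
#'   run, narrow enough to separate states a few sigma apart).
#' @param min_population minimum fraction of all points a state must hold
#'   (default 0.01, the "1% rule").
#' @param max_states safety cap on the number of peeled states.
#' @param refine if `TRUE` (default) each state's mean and spread are
#'   re-fitted once from its assigned points after peeling.
#' @param density_n grid size of the univariate kernel density estimate.
#' @return object of class `onion`: list with `states` (data.frame with
#'   `mean`, `sd` -- multivariate: `means` matrix and `cov` list --,
#'   `population`), `labels` (N x T integer, 0 = ENV0), `env0_fraction`,
#'   `delta_t`, `k_sigma`, `min_population`, `d`, `dt`, and the input
#'   `data` (for plotting). States are ordered by increasing mean
#'   (lexicographically for multivariate).
#' @seealso [delta_t_scan()], [plot.onion()], [predict.onion()]
#' @examples
#' sp <- markov_spec(c(-1, 1), 0.1,
#'                   matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE))
#' g <- gen_state_ensemble(sp, 50, 500, seed = 1)
#' fit <- onion(g$ensemble, delta_t = 10)
#' fit
#' coef(fit)
#' @export
onion <- function(x, delta_t, k_sigma = 3, min_population = 0.01,
                  max_states = 20L, refine = TRUE, density_n = 512L) {
  ens <- as.signal_ensemble(x)
  vals <- ens$values
  nd <- dim(vals)
  n <- nd[1]; tt <- nd[2]; d <- nd[3]
  if (n * tt == 0 || all(is.na(vals))) stop("empty ensemble")
  if (delta_t < 2) stop("delta_t must be >= 2 frames")
  if (delta_t > tt) stop("delta_t exceeds the trajectory length")
  if (min_population <= 0 || min_population >= 1)
    stop("min_population must lie in (0, 1)")
  if (k_sigma <= 0) stop("k_sigma must be positive")

  labels <- matrix(0L, n, tt)
  miss <- apply(is.na(vals), c(1, 2), any)
  total <- n * tt
  states <- list()

  repeat {
    avail <- labels == 0L & !miss
    npts <- sum(avail)
    if (npts < max(delta_t, ceiling(min_population * total))) break
    st <- if (d == 1) fit_peak_uni(vals[, , 1][avail], density_n)
          else fit_peak_multi(avail_points(vals, avail), k_sigma)
    if (is.null(st)) break
    cond <- if (d == 1) {
      inwin <- vals[, , 1] >= st$mean - k_sigma * st$sd &
               vals[, , 1] <= st$mean + k_sigma * st$sd
      inwin[is.na(inwin)] <- FALSE
      inwin & avail
    } else {
      md <- mahalanobis_all(vals, st$mean, st$cov)
      inwin <- md <= k_sigma^2
      inwin[is.na(inwin)] <- FALSE
      inwin & avail
    }
    runs <- run_mask(cond, delta_t)
    n_new <- sum(runs)
    if (n_new / total < min_population) break
    # a re-fitted Gaussian overlapping an already-peeled state is the same
    # state seen through its leftover tail points: merge, don't duplicate
    target <- merge_target(st, states, d)
    if (is.na(target)) {
      states[[length(states) + 1L]] <- st
      target <- length(states)
    }
    labels[runs] <- target
    if (length(states) >= max_states) break
  }

  # dissolve states that ended below the population threshold
  if (length(states)) {
    pops <- tabulate(labels[labels > 0L], nbins = length(states)) / total
    keep <- pops >= min_population
    relab <- integer(length(states))
    relab[keep] <- seq_len(sum(keep))
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    states <- states[keep]
  }

  # one refinement pass: moments of the assigned points
  if (refine && length(states)) {
    for (k in seq_along(states)) {
      sel <- labels == k
      if (d == 1) {
        pts <- vals[, , 1][sel]
        states[[k]]$mean <- mean(pts)
        states[[k]]$sd <- max(stats::sd(pts), 1e-9)
      } else {
        pts <- avail_points(vals, sel)
        tc <- stats::pchisq(k_sigma^2, d + 2) / stats::pchisq(k_sigma^2, d)
        states[[k]]$mean <- colMeans(pts)
        states[[k]]$cov <- regularize_cov(stats::cov(pts) / tc)
      }
    }
  }

  # deterministic ordering: increasing mean (lexicographic if multivariate);
  # peel_rank remembers the peeling sequence for predict()
  peel_rank <- seq_along(states)
  if (length(states) > 1) {
    key <- sapply(states, function(s) s$mean[1])
    key2 <- sapply(states, function(s) if (d > 1) s$mean[min(2, d)] else 0)
    ord <- order(key, key2)
    states <- states[ord]
    peel_rank <- ord              # original peel index of each sorted state
    old <- labels
    for (k in seq_along(ord)) labels[old == ord[k]] <- k
  }

  pops <- if (length(states))
    tabulate(labels[labels > 0L], nbins = length(states)) / total else numeric(0)
  for (k in seq_along(states)) states[[k]]$population <- pops[k]

  structure(list(states = states, labels = labels, peel_rank = peel_rank,
                 env0_fraction = mean(labels == 0L),
                 n_states = length(states),
                 delta_t = delta_t, k_sigma = k_sigma,
                 min_population = min_population, d = d, dt = ens$dt,
                 data = vals),
            class = "onion")
}

# index of an existing state whose Gaussian overlaps the new fit st
# (means closer than the larger spread), or NA when st is genuinely new
merge_target <- function(st, states, d) {
  if (!length(states)) return(NA_integer_)
  sep <- vapply(states, function(s) {
    if (d == 1) abs(st$mean - s$mean) / max(st$sd, s$sd)
    else sqrt(min(stats::mahalanobis(rbind(st$mean), s$mean, s$cov),
                  stats::mahalanobis(rbind(s$mean), st$mean, st$cov)))
  }, numeric(1))
  if (min(sep) < 1) which.min(sep) else NA_integer_
}

# rows of the N x T x d array where the N x T mask is TRUE
avail_points <- function(vals, mask) {
  d <- dim(vals)[3]
  out <- matrix(NA_real_, sum(mask), d)
  for (a in seq_len(d)) out[, a] <- vals[, , a][mask]
  out
}

mahalanobis_all <- function(vals, mu, sigma) {
  nd <- dim(vals)
  pts <- matrix(vals, nd[1] * nd[2], nd[3])
  md <- rep(NA_real_, nrow(pts))
  ok <- stats::complete.cases(pts)
  md[ok] <- stats::mahalanobis(pts[ok, , drop = FALSE], mu, sigma)
  matrix(md, nd[1], nd[2])
}

regularize_cov <- function(s, floor_sd = 1e-9) {
  e <- eigen(s, symmetric = TRUE)
  # floor is relative to the leading eigenvalue so exactly collinear
  # dimensions (e.g. a signal combined with its own copy) stay invertible
  lo <- max(floor_sd^2, max(e$values) * 1e-10)
  e$vectors %*% diag(pmax(e$values, lo), nrow(s)) %*% t(e$vectors)
}

# TRUE where a point belongs to a maximal contiguous TRUE-run of length
# >= delta_t within its row
run_mask <- function(cond, delta_t) {
  out <- matrix(FALSE, nrow(cond), ncol(cond))
  for (i in seq_len(nrow(cond))) {
    r <- rle(cond[i, ])
    long <- r$values & r$lengths >= delta_t
    if (any(long)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(long)) out[i, starts[j]:ends[j]] <- TRUE
    }
  }
  out
}

# Fit a Gaussian to the highest peak of the KDE of unassigned points.
# Returns list(mean, sd) or NULL when no usable peak exists.
fit_peak_uni <- function(pts, density_n) {
  if (length(pts) < 2) return(NULL)
  s0 <- stats::sd(pts)
  if (!is.finite(s0) || s0 < 1e-12)
    return(list(mean = mean(pts), sd = 1e-9))
  den <- stats::density(pts, bw = "nrd0", n = density_n)
  y <- den$y; x <- den$x
  ipk <- which.max(y)  # ties: which.max takes the first = lowest mean
  # flanking local minima (or domain boundaries)
  il <- ipk
  while (il > 1 && y[il - 1] < y[il]) il <- il - 1
  ir <- ipk
  while (ir < length(y) && y[ir + 1] < y[ir]) ir <- ir + 1
  idx <- il:ir
  if (length(idx) < 5) {
    sel <- pts >= x[il] & pts <= x[ir]
    if (sum(sel) < 2) return(NULL)
    return(list(mean = mean(pts[sel]), sd = max(stats::sd(pts[sel]), 1e-9)))
  }
  # half-width at half maximum as the starting spread
  half <- y[ipk] / 2
  above <- idx[y[idx] >= half]
  s_start <- max((x[max(above)] - x[min(above)]) / 2.355, diff(x[1:2]))
  fit <- tryCatch({
    df <- data.frame(xx = x[idx], yy = y[idx])
    m <- minpack.lm::nlsLM(
      yy ~ a * exp(-(xx - mu)^2 / (2 * sg^2)), data = df,
      start = list(a = y[ipk], mu = x[ipk], sg = s_start),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(m)
    # the KDE peak is the state Gaussian convolved with the kernel:
    # deconvolve the bandwidth so the spread is the state's own
    sg2 <- cf[["sg"]]^2 - den$bw^2
    list(mean = unname(cf["mu"]),
         sd = sqrt(max(sg2, (0.05 * den$bw)^2, 1e-18)))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    sel <- pts >= x[il] & pts <= x[ir]
    if (sum(sel) < 2) return(NULL)
    fit <- list(mean = mean(pts[sel]), sd = max(stats::sd(pts[sel]), 1e-9))
  }
  fit
}

# Multivariate analogue: d-dimensional histogram peak (Freedman-Diaconis
# bins per axis) seeds a trimmed-moment Gaussian with full covariance.
fit_peak_multi <- function(pts, k_sigma, n_iter = 5) {
  d <- ncol(pts)
  if (nrow(pts) < d + 2) return(NULL)
  brks <- vector("list", d)
  bin <- matrix(0L, nrow(pts), d)
  nb <- integer(d)
  for (a in seq_len(d)) {
    nbin <- max(8L, min(128L, grDevices::nclass.FD(pts[, a])))
    rng <- range(pts[, a])
    if (diff(rng) == 0) rng <- rng + c(-1, 1) * 1e-9
    brks[[a]] <- seq(rng[1], rng[2], length.out = nbin + 1L)
    bin[, a] <- pmin(pmax(findInterval(pts[, a], brks[[a]],
                                       rightmost.closed = TRUE), 1L), nbin)
    nb[a] <- nbin
  }
  cell <- bin[, 1]
  mult <- nb[1]
  if (d > 1) for (a in 2:d) { cell <- cell + (bin[, a] - 1L) * mult
                              mult <- mult * nb[a] }
  counts <- tabulate(cell, nbins = prod(nb))
  peak_cell <- which.max(counts)
  # cell -> per-axis bin of the peak, then its center
  rest <- peak_cell - 1L
  ctr <- numeric(d); wid <- numeric(d)
  for (a in seq_len(d)) {
    b <- rest %% nb[a] + 1L; rest <- rest %/% nb[a]
    ctr[a] <- (brks[[a]][b] + brks[[a]][b + 1L]) / 2
    wid[a] <- diff(brks[[a]][1:2])
  }
  sel <- rep(TRUE, nrow(pts))
  for (a in seq_len(d)) sel <- sel & abs(pts[, a] - ctr[a]) <= 1.5 * wid[a]
  if (sum(sel) < d + 2) {
    sel <- Reduce(`&`, lapply(seq_len(d),
                              function(a) abs(pts[, a] - ctr[a]) <= 3 * wid[a]))
  }
  if (sum(sel) < d + 2) return(NULL)
  mu <- colMeans(pts[sel, , drop = FALSE])
  sg <- regularize_cov(stats::cov(pts[sel, , drop = FALSE]))
  # moments of a Gaussian trimmed at Mahalanobis k underestimate the
  # covariance by the chi-square truncation factor; undo it each pass
  trunc_corr <- stats::pchisq(k_sigma^2, d + 2) / stats::pchisq(k_sigma^2, d)
  for (it in seq_len(n_iter)) {
    md <- stats::mahalanobis(pts, mu, sg)
    sel <- md <= k_sigma^2
    if (sum(sel) < d + 2) break
    mu <- colMeans(pts[sel, , drop = FALSE])
    sg <- regularize_cov(stats::cov(pts[sel, , drop = FALSE]) / trunc_corr)
  }
  list(mean = mu, cov = sg)
}

#' @export
print.onion <- function(x, ...) {
  cat(sprintf("onion clustering: %d state%s at delta_t = %d frames (dt = %g)\n",
              x$n_states, if (x$n_states == 1) "" else "s", x$delta_t, x$dt))
  cat(sprintf("  ENV0 (unclassified) fraction: %.3f\n", x$env0_fraction))
  invisible(x)
}

#' @export
summary.onion <- function(object, ...) {
  x <- object
  if (x$n_states == 0) {
    df <- data.frame(state = integer(0), mean = numeric(0),
                     spread = numeric(0), population = numeric(0))
  } else if (x$d == 1) {
    df <- data.frame(state = seq_len(x$n_states),
                     mean = sapply(x$states, `[[`, "mean"),
                     spread = sapply(x$states, `[[`, "sd"),
                     population = sapply(x$states, `[[`, "population"))
  } else {
    df <- data.frame(state = seq_len(x$n_states),
                     t(sapply(x$states, `[[`, "mean")),
                     population = sapply(x$states, `[[`, "population"))
    names(df)[2:(1 + x$d)] <- paste0("mean.", seq_len(x$d))
  }
  structure(list(states = df, env0_fraction = x$env0_fraction,
                 delta_t = x$delta_t, d = x$d), class = "summary.onion")
}

#' @export
print.summary.onion <- function(x, ...) {
  cat(sprintf("Onion clustering at delta_t = %d frames\n", x$delta_t))
  print(x$states, row.names = FALSE)
  cat(sprintf("ENV0 fraction: %.4f\n", x$env0_fraction))
  invisible(x)
}

#' @export
coef.onion <- function(object, ...) {
  if (object$n_states == 0) return(numeric(0))
  if (object$d == 1) {
    stats::setNames(sapply(object$states, `[[`, "mean"),
                    paste0("state", seq_len(object$n_states)))
  } else {
    m <- t(sapply(object$states, `[[`, "mean"))
    rownames(m) <- paste0("state", seq_len(object$n_states))
    m
  }
}

#' Classify new series against a fitted onion model
#'
#' Applies the fitted states, in their original peeling order, with the
#' model's `delta_t`, `k_sigma` and run rule to a new ensemble sampled on
#' the same clock. Because the states' means and spreads are re-fitted
#' once after peeling, re-predicting the training ensemble reproduces the
#' fitted labels up to points near state boundaries (exactly as a
#' re-assignment under the refined parameters).
#'
#' @param object a fitted [onion()] model.
#' @param newdata a [signal_ensemble()] (or matrix/array) with the same
#'   number of variables.
#' @param ... unused.
#' @return N x T integer label matrix (0 = ENV0).
#' @export
predict.onion <- function(object, newdata, ...) {
  ens <- as.signal_ensemble(newdata)
  vals <- ens$values
  if (dim(vals)[3] != object$d) stop("variable count mismatch")
  labels <- matrix(0L, dim(vals)[1], dim(vals)[2])
  miss <- apply(is.na(vals), c(1, 2), any)
  for (k in order(object$peel_rank)) {
    st <- object$states[[k]]
    cond <- if (object$d == 1) {
      vals[, , 1] >= st$mean - object$k_sigma * st$sd &
        vals[, , 1] <= st$mean + object$k_sigma * st$sd
    } else {
      mahalanobis_all(vals, st$mean, st$cov) <= object$k_sigma^2
    }
    cond[is.na(cond)] <- FALSE
    cond <- cond & labels == 0L & !miss
    labels[run_mask(cond, object$delta_t)] <- k
  }
  labels
}

#' Plot a fitted onion model
#'
#' Univariate: the kernel density of all data with each state's Gaussian
#' (scaled by its population) overlaid. Bivariate: a scatter of the pooled
#' points colored by label with state means marked.
#'
#' @param x a fitted [onion()] model.
#' @param ... passed to the underlying plot call.
#' @export
plot.onion <- function(x, ...) {
  if (x$d == 1) {
    pts <- x$data[, , 1]
    pts <- pts[!is.na(pts)]
    den <- stats::density(pts)
    graphics::plot(den, main = sprintf("Onion states (delta_t = %d)", x$delta_t),
                   xlab = "signal", ...)
    cols <- grDevices::hcl.colors(max(1, x$n_states), "Dark 2")
    for (k in seq_along(x$states)) {
      st <- x$states[[k]]
      graphics::curve(st$population * stats::dnorm(x, st$mean, st$sd),
                      add = TRUE, col = cols[k], lwd = 2)
    }
  } else {
    pts <- matrix(x$data, prod(dim(x$data)[1:2]), x$d)
    lab <- as.vector(x$labels)
    cols <- c("grey70", grDevices::hcl.colors(max(1, x$n_states), "Dark 2"))
    graphics::plot(pts[, 1], pts[, 2], col = cols[lab + 1L], pch = ".",
                   xlab = "dim 1", ylab = "dim 2",
                   main = sprintf("Onion states (delta_t = %d)", x$delta_t), ...)
    for (k in seq_along(x$states))
      graphics::points(x$states[[k]]$mean[1], x$states[[k]]$mean[2],
                       pch = 3, cex = 2, lwd = 2)
  }
  invisible(x)
}
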