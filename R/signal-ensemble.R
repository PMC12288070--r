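#' Ensemble of per-particle time series
#'
#' A `signal_ensemble` holds N time series of length T, each univariate or
#' d-variate: one signal per particle, sampled on a common clock. It is the
#' direct input to [onion()] and [delta_t_scan()]. Values are stored as an
#' N x T x d array; missing values (`NA`) mark frames where the signal is
#' undefined (e.g. an isolated particle's alignment) and are never classified.
#'
#' @param values numeric matrix (N x T, univariate) or array (N x T x d).
#' @param dt sampling interval, time per frame (default 1; stored, never used
#'   internally -- all computations run in frames).
#' @return an object of class `signal_ensemble` with elements `values`
#'   (N x T x d array) and `dt`.
#' @examples
#' x <- signal_ensemble(matrix(rnorm(200), nrow = 10), dt = 0.04)
#' dim(x$values)
#' @export
signal_ensemble <- function(values, dt = 1) {
  if (is.matrix(values)) {
    values <- array(values, dim = c(dim(values), 1L))
  }
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an N x T matrix or an N x T x d array")
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number")
  structure(list(values = values, dt = as.numeric(dt)),
            class = "signal_ensemble")
}

#' @export
print.signal_ensemble <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("signal_ensemble: %d series x %d frames x %d dim (dt = %g)\n",
              d[1], d[2], d[3], x$dt))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  %d missing values\n", n_na))
  invisible(x)
}

#' @rdname signal_ensemble
#' @param x object to coerce.
#' @export
as.signal_ensemble <- function(x, dt = 1) {
  if (inherits(x, "signal_ensemble")) return(x)
  if (inherits(x, "descriptor_series"))
    return(signal_ensemble(x$values, dt = x$dt))
  signal_ensemble(x, dt = dt)
}

n_series <- function(x) dim(x$values)[1]
n_frames_of <- function(x) dim(x$values)[2]
n_dims <- function(x) dim(x$values)[3]

#' Combine univariate ensembles into a multivariate one
#'
#' Stacks ensembles with identical N and T along the variable dimension,
#' e.g. to feed a bivariate pair of signals to [onion()].
#'
#' @param ... `signal_ensemble` objects (or matrices) with equal N and T.
#' @return a `signal_ensemble` with d equal to the total number of variables.
#' @export
bind_signals <- function(...) {
  parts <- lapply(list(...), as.signal_ensemble)
  dims <- vapply(parts, function(p) dim(p$values)[1:2], numeric(2))
  if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
    stop("all ensembles must share N and T")
  vals <- do.call(c, lapply(parts, function(p) as.vector(p$values)))
  d_tot <- sum(vapply(parts, function(p) dim(p$values)[3], numeric(1)))
  signal_ensemble(array(vals, dim = c(dims[1, 1], dims[2, 1], d_tot)),
                  dt = parts[[1]]$dt)
}

#' Number of frames obtained from a total duration and a sampling interval
#'
#' Bookkeeping helper: how many samples a trajectory of duration `total_time`
#' contains when sampled every `dt` (the convention used throughout: frame
#' times are dt, 2 dt, ..., T dt).
#'
#' @param total_time total trajectory duration (time units).
#' @param dt sampling interval (same units).
#' @return integer frame count `floor(total_time / dt)`.
#' @examples
#' n_samples(50e3, 40)  # 50 ns sampled every 40 ps -> 1250 frames
#' @export
n_samples <- function(total_time, dt) {
  stopifnot(total_time > 0, dt > 0)
  as.integer(floor(total_time / dt + 1e-9))
}
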