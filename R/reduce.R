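#' PCA of a pooled descriptor dataset
#'
#' Pools all (particle, frame) descriptor rows into one N*T x D dataset
#' (the ergodic view: temporal correlations ignored), performs covariance
#' PCA via [stats::prcomp()], and reshapes the leading `k` scores back into
#' per-particle time series ready for clustering. PC signs are fixed by
#' making the largest-magnitude loading of each component positive, so
#' results are reproducible across runs and platforms.
#'
#' @param series a [descriptor_series()] (or N x T x D array).
#' @param k number of components to keep (default 2).
#' @param scale. if `TRUE`, correlation PCA (standardize components first);
#'   default `FALSE` (covariance PCA).
#' @return object of class `descriptor_pca`: `scores` (a
#'   [signal_ensemble()] N x T x k), `rotation` (D x k loadings),
#'   `center`, `explained` (variance ratio per PC, all D), `cumulative`,
#'   and `sdev`.
#' @examples
#' toy <- gen_state_ensemble(markov_spec(c(0, 3), 0.2, diag(2)), 20, 50, 1)
#' arr <- array(c(toy$ensemble$values, -toy$ensemble$values), c(20, 50, 2))
#' p <- descriptor_pca(descriptor_series(arr), k = 1)
#' p$explained[1]  # all variance on PC1: the two components are collinear
#' @export
descriptor_pca <- function(series, k = 2, scale. = FALSE) {
  vals <- if (is.array(series)) series else series$values
  d <- dim(vals)
  rows <- matrix(vals, nrow = d[1] * d[2], ncol = d[3])
  if (nrow(rows) < 2) stop("need at least 2 descriptor rows for PCA")
  k <- min(k, d[3])
  keep_sd <- apply(rows, 2, stats::sd)
  if (isTRUE(scale.) && any(keep_sd == 0))
    stop("cannot standardize zero-variance components")
  pc <- stats::prcomp(rows, center = TRUE, scale. = scale.)
  # deterministic sign: largest-|loading| entry of each PC made positive
  for (j in seq_len(ncol(pc$rotation))) {
    i_big <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_big, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_pc <- pc$sdev^2
  explained <- var_pc / sum(var_pc)
  dt <- if (!is.null(series$dt)) series$dt else 1
  scores <- signal_ensemble(array(pc$x[, seq_len(k)], c(d[1], d[2], k)),
                            dt = dt)
  structure(list(scores = scores, rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, explained = explained,
                 cumulative = cumsum(explained), sdev = pc$sdev),
            class = "descriptor_pca")
}

#' @export
print.descriptor_pca <- function(x, ...) {
  k <- dim(x$scores$values)[3]
  cat(sprintf("descriptor_pca: %d scores kept of %d components\n",
              k, length(x$explained)))
  cat("  explained variance ratio:",
      paste(sprintf("PC%d %.3f", seq_len(min(4, length(x$explained))),
                    x$explained[seq_len(min(4, length(x$explained)))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-component variance report
#'
#' Variance of every raw descriptor component over all (particle, frame)
#' samples, ranked descending, with each component tagged by its family
#' (spherical l = 0 vs angular l > 0) when SOAP metadata is available.
#' High variance does not imply high relevance: low-variance angular
#' components can carry the discriminating signal.
#'
#' @param series a [descriptor_series()].
#' @return data.frame with columns `index` (0-based flat component index),
#'   `variance`, `rank`, and -- when SOAP params are attached -- `n`,
#'   `n_prime`, `l`, `family`.
#' @export
component_variances <- function(series) {
  vals <- if (is.array(series)) series else series$values
  d <- dim(vals)
  rows <- matrix(vals, nrow = d[1] * d[2], ncol = d[3])
  v <- apply(rows, 2, stats::var)
  out <- data.frame(index = seq_len(d[3]) - 1L, variance = v)
  out$rank <- rank(-v, ties.method = "first")
  p <- if (!is.array(series)) series$params else NULL
  if (inherits(p, "soap_params") && soap_n_components(p) == d[3]) {
    nnl <- soap_index_to_nnl(out$index, p)
    out$n <- nnl$n; out$n_prime <- nnl$n_prime; out$l <- nnl$l
    out$family <- ifelse(nnl$l == 0L, "l=0", "l>0")
  }
  out
}

#' Extract one descriptor component as a univariate ensemble
#'
#' @param series a [descriptor_series()].
#' @param index 0-based flat component index (matching the `#k` component
#'   naming and [soap_component_index()]).
#' @return a [signal_ensemble()] (N x T).
#' @examples
#' # component #63 of an n_max = l_max = 8 SOAP series is (n=8, n'=8, l=0)
#' @export
extract_component <- function(series, index) {
  vals <- if (is.array(series)) series else series$values
  d <- dim(vals)
  if (length(index) != 1 || index < 0 || index >= d[3])
    stop("component index out of range")
  dt <- if (!is.array(series) && !is.null(series$dt)) series$dt else 1
  signal_ensemble(matrix(vals[, , index + 1], d[1], d[2]), dt = dt)
}
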