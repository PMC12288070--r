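#' Run the full analysis pipeline
#'
#' Ties the stages together: obtain a trajectory (from a generator or a
#' file), compute a per-particle descriptor (SOAP power spectra, minimum
#' neighbor distance, or local velocity alignment), optionally denoise it
#' spatially, select a signal (a PCA score or a single component), scan
#' the onion clustering across time resolutions, and write every artifact
#' -- scan CSV, state table, label CSV, resolved configuration and log --
#' into `out_dir`. Deterministic for a fixed `seed`.
#'
#' @param config nested list (or path to a JSON file) with entries:
#' \describe{
#'   \item{seed}{master seed for the generators.}
#'   \item{input}{either `list(generate = "two_phase"|"wave", args = ...)`
#'     or `list(path = "traj.xyz")`.}
#'   \item{descriptor}{`list(type = "soap"|"dmin"|"phi", ...)` with SOAP
#'     parameters or the alignment cutoff `r_c`.}
#'   \item{denoise}{optional `list(cutoff = ...)`.}
#'   \item{signal}{`list(pca = k)` to cluster the k-th PC score, or
#'     `list(component = i)` for a 0-based descriptor component, or
#'     omitted for already-univariate descriptors.}
#'   \item{onion}{optional `list(grid = ..., k_sigma = ..., ...)`.}
#' }
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the trajectory, descriptor series,
#'   clustered signal and `delta_t` scan.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  seed <- config$seed %||% 1L
  logf("[input] seed = %d", seed)

  # --- stage 1: trajectory -------------------------------------------------
  inp <- config$input
  if (!is.null(inp$generate)) {
    args <- c(inp$args, list(seed = seed))
    gen <- switch(inp$generate,
                  two_phase = do.call(gen_two_phase_toy, args),
                  wave = do.call(gen_wave_toy, args),
                  stop("unknown generator: ", inp$generate))
    traj <- gen$traj
    utils::write.csv(data.frame(particle = seq_len(nrow(gen$labels)),
                                gen$labels),
                     file.path(out_dir, "ground_truth_labels.csv"),
                     row.names = FALSE)
  } else if (!is.null(inp$path)) {
    traj <- read_trajectory(inp$path)
  } else stop("stage input: need either `generate` or `path`")
  write_trajectory(traj, file.path(out_dir, "trajectory.xyz"))
  logf("[trajectory] %d particles x %d frames", dim(traj$positions)[1],
       dim(traj$positions)[2])

  # --- stage 2: descriptor -------------------------------------------------
  desc_cfg <- config$descriptor %||% list(type = "soap")
  series <- switch(desc_cfg$type,
    soap = {
      p <- do.call(soap_params,
                   desc_cfg[intersect(names(desc_cfg),
                                      names(formals(soap_params)))])
      soap_descriptors(traj, p)
    },
    dmin = min_neighbor_distance(traj),
    phi = {
      if (is.null(traj$velocities)) traj <- velocities_from_positions(traj)
      local_alignment(traj, desc_cfg$r_c %||% 15)
    },
    stop("unknown descriptor type: ", desc_cfg$type))
  logf("[descriptor] type = %s", desc_cfg$type)

  # --- stage 3: spatial denoising ------------------------------------------
  if (!is.null(config$denoise)) {
    series <- spatial_average(series, traj, config$denoise$cutoff)
    logf("[denoise] cutoff = %g", config$denoise$cutoff)
  }

  # --- stage 4: signal selection -------------------------------------------
  sig_cfg <- config$signal
  signal <- if (inherits(series, "signal_ensemble")) {
    series
  } else if (!is.null(sig_cfg$pca)) {
    pc <- descriptor_pca(series, k = sig_cfg$pca)
    utils::write.csv(data.frame(pc = seq_along(pc$explained),
                                explained = pc$explained,
                                cumulative = pc$cumulative),
                     file.path(out_dir, "pca_variance.csv"),
                     row.names = FALSE)
    extract_component(list(values = pc$scores$values, dt = pc$scores$dt),
                      sig_cfg$pca - 1)
  } else if (!is.null(sig_cfg$component)) {
    extract_component(series, sig_cfg$component)
  } else {
    vr <- component_variances(series)
    extract_component(series, vr$index[which.min(vr$rank)])
  }
  write_ensemble_csv(signal, file.path(out_dir, "signal.csv"),
                     stage = "signal-selection")

  # --- stage 5: onion scan -------------------------------------------------
  onion_cfg <- config$onion %||% list()
  grid <- onion_cfg$grid
  onion_args <- onion_cfg[setdiff(names(onion_cfg), "grid")]
  scan <- do.call(delta_t_scan, c(list(signal, grid = grid), onion_args))
  utils::write.csv(as.data.frame(scan), file.path(out_dir, "scan.csv"),
                   row.names = FALSE)
  best <- scan$delta_t_frames[which.max(scan$n_states)]
  fit <- do.call(onion, c(list(signal, delta_t = best), onion_args))
  utils::write.csv(summary(fit)$states, file.path(out_dir, "states.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(particle = seq_len(nrow(fit$labels)),
                              fit$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  logf("[onion] best delta_t = %d frames: %d states, env0 = %.3f",
       best, fit$n_states, fit$env0_fraction)

  cfg_out <- config
  cfg_out$seed <- seed
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(traj = traj, series = series, signal = signal,
                 scan = scan, fit = fit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
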