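#' Read a particle trajectory
#'
#' Reads extended XYZ (one block per frame: count line, comment line with
#' `Lattice="..."`, `Properties=...` and optionally `pbc="..."` and `dt=...`,
#' then one row per particle) or long-format CSV with columns
#' `particle_id, frame, x, y[, z][, vx, vy[, vz]]`. Only orthorhombic lattices
#' are supported; the box is taken from the diagonal of the lattice matrix.
#'
#' @param path file to read.
#' @param format `"xyz"`, `"csv"` or `"auto"` (by extension).
#' @param dt sampling interval override; `NA` keeps the file's value (XYZ
#'   `dt=` field) or 1.
#' @return a [particle_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "csv"), dt = NA) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "xyz"
  }
  traj <- if (format == "xyz") read_xyz(path) else read_tracks_csv(path)
  if (!is.na(dt)) traj$dt <- dt
  traj
}

read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); vels <- list()
  box <- NULL; periodic <- NULL; dt <- 1
  i <- 1L; f <- 0L; n0 <- NA_integer_
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("line %d: expected particle count, got '%s'", i, lines[i]))
    if (is.na(n0)) n0 <- n
    if (n != n0)
      stop(sprintf("line %d: particle count %d differs from first frame (%d)",
                   i, n, n0))
    if (i + 1L > length(lines)) stop(sprintf("line %d: missing comment line", i + 1L))
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat) == 2) {
      m <- matrix(as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]]), 3, 3,
                  byrow = TRUE)
      off <- m; diag(off) <- 0
      if (any(abs(off) > 1e-10)) stop("only orthorhombic lattices are supported")
      box <- diag(m)
    }
    pbc <- regmatches(comment, regexec('pbc="([^"]+)"', comment))[[1]]
    if (length(pbc) == 2)
      periodic <- toupper(strsplit(trimws(pbc[2]), "\\s+")[[1]]) %in% c("T", "TRUE")
    dtf <- regmatches(comment, regexec('dt=([0-9eE.+-]+)', comment))[[1]]
    if (length(dtf) == 2) dt <- as.numeric(dtf[2])
    has_vel <- grepl("vel:R:3", comment, fixed = TRUE)
    rows <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rows), "\\s+")
    ncol_row <- lengths(fields)
    if (any(ncol_row < 4))
      stop(sprintf("line %d: malformed atom line", i + 1L + which(ncol_row < 4)[1]))
    num <- t(vapply(fields, function(z) as.numeric(z[-1]), numeric(ncol_row[1] - 1L)))
    f <- f + 1L
    frames[[f]] <- num[, 1:3, drop = FALSE]
    if (has_vel && ncol(num) >= 6) vels[[f]] <- num[, 4:6, drop = FALSE]
    i <- i + 2L + n
  }
  tt <- length(frames)
  pos <- array(NA_real_, c(n0, tt, 3))
  for (t in seq_len(tt)) pos[, t, ] <- frames[[t]]
  vel <- NULL
  if (length(vels) == tt && tt > 0) {
    vel <- array(NA_real_, c(n0, tt, 3))
    for (t in seq_len(tt)) vel[, t, ] <- vels[[t]]
  }
  if (is.null(box)) box <- apply(pos, 3, function(z) max(z) - min(z) + 1)
  if (is.null(periodic)) periodic <- rep(FALSE, 3)
  particle_trajectory(pos, vel, box = box, periodic = periodic, dt = dt)
}

read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("particle_id", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("CSV must have columns particle_id, frame, x, y[, z][, vx, vy[, vz]]")
  ndim <- if ("z" %in% names(df)) 3L else 2L
  ids <- sort(unique(df$particle_id))
  fr <- sort(unique(df$frame))
  n <- length(ids); tt <- length(fr)
  ii <- match(df$particle_id, ids); jj <- match(df$frame, fr)
  coord_cols <- c("x", "y", "z")[seq_len(ndim)]
  pos <- array(NA_real_, c(n, tt, ndim))
  for (a in seq_len(ndim)) pos[cbind(ii, jj, a)] <- df[[coord_cols[a]]]
  if (anyNA(pos)) stop("incomplete trajectory: every particle needs every frame")
  vel <- NULL
  vel_cols <- c("vx", "vy", "vz")[seq_len(ndim)]
  if (all(vel_cols %in% names(df))) {
    vel <- array(NA_real_, c(n, tt, ndim))
    for (a in seq_len(ndim)) vel[cbind(ii, jj, a)] <- df[[vel_cols[a]]]
  }
  box <- apply(pos, 3, function(z) max(z) * 1.001)
  particle_trajectory(pos, vel, box = box, periodic = FALSE, dt = 1)
}

#' Write a particle trajectory as extended XYZ
#'
#' One block per frame with `Lattice`, `Properties` and `pbc` comment fields;
#' velocities, when present, are written as three extra columns.
#'
#' @param traj a `particle_trajectory` (2D trajectories are padded with z = 0).
#' @param path output file.
#' @param species atom label for every particle (single species).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, species = "X") {
  stopifnot(inherits(traj, "particle_trajectory"))
  d <- dim(traj$positions)
  n <- d[1]; tt <- d[2]; ndim <- d[3]
  pad <- function(m) if (ncol(m) == 2) cbind(m, 0) else m
  box3 <- if (ndim == 2) c(traj$box, 1) else traj$box
  per3 <- if (ndim == 2) c(traj$periodic, FALSE) else traj$periodic
  lat <- sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g"', box3[1], box3[2], box3[3])
  pbc <- sprintf('pbc="%s"', paste(ifelse(per3, "T", "F"), collapse = " "))
  has_vel <- !is.null(traj$velocities)
  props <- if (has_vel) "Properties=species:S:1:pos:R:3:vel:R:3"
           else "Properties=species:S:1:pos:R:3"
  con <- file(path, "w"); on.exit(close(con))
  for (t in seq_len(tt)) {
    writeLines(as.character(n), con)
    writeLines(paste(lat, props, pbc, sprintf("dt=%.10g", traj$dt)), con)
    p <- pad(matrix(traj$positions[, t, ], nrow = n))
    body <- sprintf("%s %.10g %.10g %.10g", species, p[, 1], p[, 2], p[, 3])
    if (has_vel) {
      v <- pad(matrix(traj$velocities[, t, ], nrow = n))
      body <- sprintf("%s %.10g %.10g %.10g", body, v[, 1], v[, 2], v[, 3])
    }
    writeLines(body, con)
  }
  invisible(path)
}

#' Write / read a signal ensemble as long-format CSV
#'
#' Columns `series_id, frame, value` (univariate) or `value.1 ... value.d`.
#' A comment header records the sampling interval and producing stage.
#'
#' @param x a `signal_ensemble`.
#' @param path file path.
#' @param stage free-text provenance written into the header.
#' @return `path` invisibly; `read_ensemble_csv` returns a `signal_ensemble`.
#' @export
write_ensemble_csv <- function(x, path, stage = "dynenv") {
  x <- as.signal_ensemble(x)
  d <- dim(x$values)
  df <- data.frame(series_id = rep(seq_len(d[1]), d[2]),
                   frame = rep(seq_len(d[2]), each = d[1]))
  if (d[3] == 1) {
    df$value <- as.vector(x$values[, , 1])
  } else {
    for (k in seq_len(d[3])) df[[paste0("value.", k)]] <- as.vector(x$values[, , k])
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# dynenv signal_ensemble; dt=%.10g (time units per frame); stage=%s",
                     x$dt, stage), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  first <- readLines(path, n = 1)
  dt <- 1
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("dt=([0-9eE.+-]+)", first))[[1]]
    if (length(m) == 2) dt <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  ids <- sort(unique(df$series_id)); fr <- sort(unique(df$frame))
  vcols <- grep("^value", names(df), value = TRUE)
  arr <- array(NA_real_, c(length(ids), length(fr), length(vcols)))
  ii <- match(df$series_id, ids); jj <- match(df$frame, fr)
  for (k in seq_along(vcols)) arr[cbind(ii, jj, k)] <- df[[vcols[k]]]
  signal_ensemble(arr, dt = dt)
}
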