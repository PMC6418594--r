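#' Write a trajectory as frame-blocked XYZ with a metadata sidecar
#'
#' The XYZ file holds one block per frame (`n_particles`, a comment line,
#' then `element x y z` per particle). Frame spacing, per-frame box and
#' the wrapped flag, which plain XYZ cannot carry, go to a YAML sidecar at
#' `<path>.meta.yaml`.
#'
#' @param traj a `Trajectory`.
#' @param path output XYZ path.
#' @param elements per-particle element labels (default `"C"`).
#' @param digits coordinate precision written (default 6 decimals).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, elements = NULL, digits = 6L) {
  stopifnot(inherits(traj, "Trajectory"))
  elements <- elements %||% rep("C", traj$n_particles)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (f in seq_len(traj$n_frames)) {
    writeLines(as.character(traj$n_particles), con)
    writeLines(sprintf("frame %d", f - 1L), con)
    xyz <- matrix(traj$coords[f, , ], ncol = 3L)
    writeLines(sprintf(fmt, elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  meta <- list(dt = traj$dt, wrapped = traj$wrapped,
               box = lapply(seq_len(nrow(traj$box)),
                            function(i) as.numeric(traj$box[i, ])))
  if (!is.null(traj$masses)) meta$masses <- as.numeric(traj$masses)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a frame-blocked XYZ trajectory
#'
#' Counterpart of [write_xyz()]. The sidecar `<path>.meta.yaml` supplies
#' `dt`, the per-frame (or constant) `box` and the `wrapped` flag; when it
#' is absent, `dt` and `box` must be given explicitly.
#'
#' @param path XYZ file path.
#' @param dt,box,wrapped overrides for the sidecar metadata.
#' @return a `Trajectory`.
#' @export
read_xyz <- function(path, dt = NULL, box = NULL, wrapped = NULL) {
  if (!file.exists(path))
    abort_validation("trajectory file '%s' does not exist", path)
  lines <- readLines(path)
  if (length(lines) < 3L)
    abort_validation("'%s' is not a frame-blocked XYZ file", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    abort_validation("'%s': first line must be the particle count", path)
  block <- n + 2L
  n_frames <- length(lines) %/% block
  if (n_frames * block != length(lines))
    abort_validation("'%s': truncated XYZ frame block", path)
  coords <- array(NA_real_, dim = c(n_frames, n, 3L))
  for (f in seq_len(n_frames)) {
    off <- (f - 1L) * block
    body <- lines[(off + 3L):(off + block)]
    parts <- strsplit(trimws(body), "\\s+")
    m <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3L))
    coords[f, , ] <- t(m)
  }
  masses <- NULL
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    dt <- dt %||% meta$dt
    wrapped <- wrapped %||% meta$wrapped
    if (is.null(box) && !is.null(meta$box)) {
      b <- meta$box
      box <- if (is.list(b)) do.call(rbind, lapply(b, as.numeric)) else as.numeric(b)
    }
    masses <- if (!is.null(meta$masses)) as.numeric(meta$masses)
  }
  if (is.null(dt) || is.null(box))
    abort_validation("'%s': no sidecar metadata; supply dt and box", path)
  trajectory(coords, box = box, dt = dt,
             wrapped = isTRUE(wrapped %||% TRUE), masses = masses)
}

read_dcd_trajectory <- function(path, topology, dt, wrapped) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort_validation("reading DCD trajectories requires the 'bio3d' package")
  hdr <- bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)
  xyz <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
  n_frames <- nrow(xyz)
  n <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(n_frames, n, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * n, by = 3L), drop = FALSE]
  # bio3d cell rows: a, b, c lengths then angles
  ang <- hdr[, 4:6, drop = FALSE]
  if (any(abs(ang - 90) > 1e-3))
    abort_validation("non-orthorhombic cell: only orthorhombic boxes are supported")
  box <- hdr[, 1:3, drop = FALSE]
  masses <- NULL
  if (!is.null(topology)) {
    pdb <- bio3d::read.pdb(topology)
    elem <- pdb$atom$elesy
    known <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
               P = 30.974, S = 32.06, F = 18.998)
    m <- known[toupper(elem)]
    if (!anyNA(m) && length(m) == n) masses <- unname(m)
  }
  trajectory(coords, box = box, dt = dt, wrapped = wrapped, masses = masses)
}

#' Load a trajectory and its group definitions
#'
#' Dispatches on the trajectory file extension: `.xyz` uses the package's
#' frame-blocked plain-text reader (with YAML sidecar metadata), `.dcd`
#' uses the binary CHARMM/NAMD reader from \pkg{bio3d} (an optional PDB
#' topology supplies element masses). Other formats raise an explicit
#' unsupported-format error. The group file is validated against the
#' particle count; a `dt` key in the group file overrides the trajectory
#' frame spacing.
#'
#' @param path trajectory file.
#' @param topology optional topology file (PDB) for binary formats.
#' @param group_file YAML group file, see [read_group_file()].
#' @param dt,wrapped metadata overrides.
#' @return `list(trajectory = <Trajectory>, groups = <GroupSpec>)`.
#' @export
load_trajectory <- function(path, topology = NULL, group_file = NULL,
                            dt = NULL, wrapped = TRUE) {
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
    xyz = read_xyz(path, dt = dt),
    dcd = {
      if (is.null(dt))
        abort_validation("DCD carries no time metadata: supply dt (ns)")
      read_dcd_trajectory(path, topology, dt = dt, wrapped = wrapped)
    },
    abort_validation(
      "unsupported trajectory format '.%s' (supported: .xyz, .dcd)", ext)
  )
  groups <- NULL
  if (!is.null(group_file)) {
    groups <- read_group_file(group_file, n_particles = traj$n_particles)
    dt_override <- attr(groups, "dt")
    if (!is.null(dt_override)) traj$dt <- dt_override
  }
  list(trajectory = traj, groups = groups)
}
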