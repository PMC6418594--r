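#' Trajectory objects
#'
#' A `Trajectory` holds per-frame particle coordinates of a molecular
#' simulation together with the periodic cell and the frame spacing. Only
#' orthorhombic cells are supported; coordinates are in Angstrom and times
#' in nanoseconds throughout the package.
#'
#' @param coords numeric array of dimension `c(n_frames, n_particles, 3)`,
#'   coordinates in Angstrom.
#' @param box per-frame orthorhombic box lengths (Angstrom): either a
#'   length-3 vector (constant cell) or an `n_frames x 3` matrix.
#' @param dt time between stored frames in nanoseconds.
#' @param wrapped logical flag: `TRUE` if every coordinate lies inside the
#'   primary cell `[0, L)`.
#' @param masses optional per-particle masses; `NULL` means uniform.
#'
#' @return An object of class `"Trajectory"`: a list with elements
#'   `coords`, `box`, `dt`, `wrapped`, `masses`, `n_frames`, `n_particles`.
#' @export
trajectory <- function(coords, box, dt, wrapped = TRUE, masses = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    abort_validation("'coords' must be an n_frames x n_particles x 3 array")
  n_frames <- dim(coords)[1]
  n_particles <- dim(coords)[2]
  if (is.null(dim(box))) {
    if (length(box) != 3L)
      abort_validation("'box' must be length 3 or an n_frames x 3 matrix")
    box <- matrix(box, nrow = n_frames, ncol = 3L, byrow = TRUE)
  }
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3L)
    abort_validation("'box' must be length 3 or an n_frames x 3 matrix")
  if (any(!is.finite(box)) || any(box <= 0))
    abort_validation("all box lengths must be positive and finite")
  assert_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  if (!is.null(masses)) {
    if (length(masses) != n_particles || any(masses <= 0))
      abort_validation("'masses' must have one positive entry per particle")
  }
  structure(
    list(coords = coords, box = box, dt = dt, wrapped = isTRUE(wrapped),
         masses = masses, n_frames = n_frames, n_particles = n_particles),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "<Trajectory> %d frames x %d particles, dt = %g ns, %s\n",
    x$n_frames, x$n_particles, x$dt,
    if (x$wrapped) "wrapped" else "unwrapped"))
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Frame times of a trajectory
#'
#' @param traj a `Trajectory`.
#' @return numeric vector `0, dt, ..., (n_frames-1)*dt` in ns.
#' @export
frame_times <- function(traj) {
  (seq_len(traj$n_frames) - 1) * traj$dt
}

#' Unwrap periodic coordinates
#'
#' Converts wrapped coordinates into continuous trajectories by
#' accumulating per-frame minimum-image displacements. Valid when no
#' particle moves half a box length or more between stored frames; a
#' larger apparent jump triggers a warning naming the frame and particle,
#' since the unwrapping is then ambiguous.
#'
#' @param traj a wrapped `Trajectory`.
#' @return an unwrapped `Trajectory`; frame 1 is unchanged.
#' @export
unwrap <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  if (!traj$wrapped)
    abort_validation("trajectory is already unwrapped")
  out <- traj$coords
  if (traj$n_frames > 1L) {
    for (f in 2:traj$n_frames) {
      raw <- traj$coords[f, , , drop = TRUE] - traj$coords[f - 1L, , , drop = TRUE]
      if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
      disp <- min_image(raw, traj$box[f, ])
      big <- which(abs(disp) >= matrix(traj$box[f, ] / 2 - 1e-12,
                                       nrow = nrow(disp), ncol = 3L, byrow = TRUE),
                   arr.ind = TRUE)
      if (nrow(big) > 0L)
        warning(sprintf(
          "displacement >= half box at frame %d, particle %d: unwrap ambiguous",
          f, big[1, 1]), call. = FALSE)
      out[f, , ] <- out[f - 1L, , , drop = TRUE] + disp
    }
  }
  traj$coords <- out
  traj$wrapped <- FALSE
  traj
}

#' Re-wrap coordinates into the primary cell
#'
#' Inverse of [unwrap()]: maps every coordinate back into `[0, L)`.
#'
#' @param traj a `Trajectory`.
#' @return a wrapped `Trajectory`.
#' @export
rewrap <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  for (f in seq_len(traj$n_frames)) {
    traj$coords[f, , ] <- wrap_coords(
      matrix(traj$coords[f, , ], ncol = 3L), traj$box[f, ])
  }
  traj$wrapped <- TRUE
  traj
}

#' Center of mass of a particle group per frame
#'
#' Mass-weighted mean position of the indexed particles in every frame.
#' When the trajectory carries no masses (or `weighted = FALSE`) a plain
#' mean is used.
#'
#' @param traj a `Trajectory`.
#' @param indices particle indices (1-based) of the group.
#' @param weighted use trajectory masses when available (default `TRUE`).
#' @return an `n_frames x 3` matrix of COM coordinates (Angstrom).
#' @export
group_com <- function(traj, indices, weighted = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  indices <- as.integer(indices)
  if (length(indices) == 0L)
    abort_validation("group index set is empty")
  if (any(indices < 1L) || any(indices > traj$n_particles))
    abort_validation("group indices out of range 1..%d", traj$n_particles)
  w <- if (weighted && !is.null(traj$masses)) traj$masses[indices]
       else rep(1, length(indices))
  w <- w / sum(w)
  com <- matrix(0, traj$n_frames, 3L)
  for (k in 1:3) {
    xk <- matrix(traj$coords[, indices, k], nrow = traj$n_frames)
    com[, k] <- as.vector(xk %*% w)
  }
  com
}

#' Remove the drift of a reference group
#'
#' Translates every frame so the reference group's center of mass stays at
#' its frame-1 position. Used to remove collective drift (e.g. of the
#' lipid phase or of the whole system) before computing displacements or
#' axial profiles. Relative intra-frame geometry is unchanged.
#'
#' @param traj an unwrapped `Trajectory`.
#' @param reference indices of the reference group.
#' @param weighted mass-weight the reference COM (default `TRUE`).
#' @return a `Trajectory` in which the reference COM is constant.
#' @export
subtract_com_motion <- function(traj, reference, weighted = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  if (traj$wrapped)
    abort_validation("unwrap the trajectory before subtracting COM motion")
  com <- group_com(traj, reference, weighted = weighted)
  shift <- sweep(com, 2L, com[1L, ])
  for (k in 1:3) {
    traj$coords[, , k] <- traj$coords[, , k] - shift[, k]
  }
  traj
}
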