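#' Synthetic trajectory generators
#'
#' Seeded generators that emulate the statistical structure each analysis
#' stage assumes, with known ground truth, so the whole pipeline can be
#' validated by parameter recovery without running molecular dynamics.
#' Defaults mirror the simulated study system: a 288-lipid DPPC bilayer
#' (144 per leaflet) hosting 6 polyphilic additives in a 98 x 98 x 68 A
#' cell, sampled every 0.1 ns.
#'
#' @name synthetic
NULL

#' Lateral Brownian walkers
#'
#' Generates independent 2D Brownian walkers confined to a plane:
#' each step increments x and y by independent Gaussian displacements of
#' variance `2 * D * dt` (D converted from 1e-12 m^2/s to A^2/ns), plus
#' an optional collective drift. Optionally appends a second population
#' of "additive" walkers with their own diffusivity, emulating a doped
#' bilayer whose additives are referenced to the lipid COM.
#'
#' @param n_walkers number of lipid-like walkers.
#' @param d_true their diffusion coefficient (1e-12 m^2/s).
#' @param dt frame spacing (ns).
#' @param n_steps number of stored frames (>= 2).
#' @param box lateral box length (Angstrom, square cell).
#' @param drift lateral drift velocity, length-2 (Angstrom/ns).
#' @param z_plane constant z assigned to all walkers (Angstrom).
#' @param n_additives optional count of additive-like walkers appended.
#' @param d_additive their diffusivity (1e-12 m^2/s); defaults to `d_true`.
#' @param seed RNG seed.
#' @return `list(trajectory, groups)`: a wrapped `Trajectory` and a
#'   `GroupSpec` with `lipids` = the first population and `additives` =
#'   the appended one (each additive a degenerate one-atom molecule).
#' @export
gen_brownian2d <- function(n_walkers = 288, d_true = 13.9, dt = 0.1,
                           n_steps = 1000, box = 98, drift = c(0, 0),
                           z_plane = 34, n_additives = 0, d_additive = NULL,
                           seed = 1) {
  assert_scalar_number(d_true, "d_true", lower = 0)
  assert_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  assert_scalar_number(box, "box", lower = 0, strict = TRUE)
  if (n_steps < 2L) abort_validation("'n_steps' must be >= 2")
  d_additive <- d_additive %||% d_true
  set.seed(seed)
  n_tot <- n_walkers + n_additives
  sd_per <- sqrt(2 * c(rep(d_true, n_walkers), rep(d_additive, n_additives)) *
                   D_UNIT_A2_NS * dt)
  coords <- array(0, dim = c(n_steps, n_tot, 3L))
  x0 <- matrix(stats::runif(n_tot * 2L, 0, box), n_tot, 2L)
  coords[1, , 1:2] <- x0
  coords[, , 3] <- z_plane
  drift_step <- drift * dt
  for (f in 2:n_steps) {
    step <- matrix(stats::rnorm(n_tot * 2L, sd = sd_per), n_tot, 2L)
    coords[f, , 1:2] <- coords[f - 1L, , 1:2] + step +
      matrix(drift_step, n_tot, 2L, byrow = TRUE)
  }
  box3 <- c(box, box, max(box, 2 * abs(z_plane) + 1))
  traj <- trajectory(coords, box = box3, dt = dt, wrapped = FALSE)
  traj <- rewrap(traj)
  add_idx <- if (n_additives > 0) (n_walkers + 1L):n_tot else integer()
  mols <- lapply(add_idx, function(i)
    stats::setNames(rep(list(i), length(mol_roles)), mol_roles))
  groups <- group_spec(lipids = seq_len(n_walkers), additives = add_idx,
                       molecules = mols, n_particles = n_tot)
  list(trajectory = traj, groups = groups)
}

#' Trimer cluster frames
#'
#' Each frame contains one triangle of molecular-center (COR) points with
#' side lengths `(pair_distance, pair_distance, third_distance)`,
#' isotropic Gaussian jitter per coordinate, a random in-plane rotation
#' and placement, plus `n_outside` background molecules placed uniformly
#' at random in the lateral cell. All points share one base z. Defaults
#' reproduce the nearest- and second-neighbour COR spacings of the
#' simulated trimer (7 and 12 Angstrom).
#'
#' @param pair_distance nearest-neighbour COR spacing (Angstrom).
#' @param third_distance second-neighbour spacing (Angstrom); must satisfy
#'   `pair_distance <= third_distance < 2 * pair_distance`.
#' @param jitter_sigma Gaussian jitter per coordinate (Angstrom).
#' @param n_outside background molecules per frame.
#' @param min_separation background points are re-drawn until at least
#'   this far (laterally) from all other points; 0 disables.
#' @param n_frames,box,z_plane,seed frame count, lateral box, base z, seed.
#' @return `list(trajectory, groups)`; the first three molecules are the
#'   trimer, the rest background. Each molecule is a one-point marker
#'   carrying all structural roles.
#' @export
gen_cluster_frames <- function(pair_distance = 7, third_distance = 12,
                               jitter_sigma = 0, n_outside = 3,
                               min_separation = 0, n_frames = 100,
                               box = 98, z_plane = 34, seed = 1) {
  assert_scalar_number(pair_distance, "pair_distance", lower = 0, strict = TRUE)
  assert_scalar_number(jitter_sigma, "jitter_sigma", lower = 0)
  if (third_distance < pair_distance)
    abort_validation("'third_distance' must be >= 'pair_distance'")
  if (third_distance >= 2 * pair_distance)
    abort_validation(
      "triangle inequality violated: third_distance must be < 2*pair_distance")
  set.seed(seed)
  p <- pair_distance; t3 <- third_distance
  theta <- acos((2 * p^2 - t3^2) / (2 * p^2))  # apex angle, law of cosines
  base <- rbind(c(0, 0), c(p, 0), p * c(cos(theta), sin(theta)))
  n_mol <- 3L + n_outside
  coords <- array(0, dim = c(n_frames, n_mol, 3L))
  coords[, , 3] <- z_plane
  for (f in seq_len(n_frames)) {
    phi <- stats::runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
    centre <- stats::runif(2L, 0, box)
    tri <- sweep(base %*% rot, 2L, centre, "+")
    pts <- tri
    for (j in seq_len(n_outside)) {
      repeat {
        cand <- stats::runif(2L, 0, box)
        if (min_separation <= 0) break
        d <- min_image(sweep(pts, 2L, cand), c(box, box))
        if (min(sqrt(rowSums(d^2))) >= min_separation) break
      }
      pts <- rbind(pts, cand)
    }
    coords[f, , 1:2] <- pts
    if (jitter_sigma > 0)
      coords[f, , ] <- coords[f, , ] +
        stats::rnorm(n_mol * 3L, sd = jitter_sigma)
  }
  traj <- trajectory(coords, box = c(box, box, max(box, 2 * z_plane + 1)),
                     dt = 1, wrapped = FALSE)
  mols <- lapply(seq_len(n_mol), function(i)
    stats::setNames(rep(list(i), length(mol_roles)), mol_roles))
  groups <- group_spec(additives = seq_len(n_mol), molecules = mols,
                       n_particles = n_mol)
  list(trajectory = traj, groups = groups)
}

#' Terminal-group contact pairs
#'
#' Frames of point pairs at a fixed contact spacing with Gaussian jitter,
#' plus uniform background points, emulating the short-range contact
#' structure of CH3 or CF3 side-chain terminal carbons. Default contact
#' distances are 3 Angstrom (`"ch3"`) and 5 Angstrom (`"cf3"`).
#'
#' @param kind `"ch3"` or `"cf3"`, selecting the default spacing.
#' @param distance contact distance (Angstrom); overrides `kind`.
#' @param jitter_sigma Gaussian jitter per coordinate (Angstrom).
#' @param n_pairs pairs per frame.
#' @param n_outside uniform background points per frame.
#' @param n_frames,box,seed frame count, cubic box length, seed.
#' @return `list(trajectory, groups)` with `additives` = all points.
#' @export
gen_terminal_pairs <- function(kind = c("ch3", "cf3"), distance = NULL,
                               jitter_sigma = 0.3, n_pairs = 3,
                               n_outside = 2, n_frames = 500, box = 60,
                               seed = 1) {
  kind <- match.arg(kind)
  distance <- distance %||% c(ch3 = 3, cf3 = 5)[[kind]]
  assert_scalar_number(distance, "distance", lower = 0, strict = TRUE)
  set.seed(seed)
  n_pts <- 2L * n_pairs + n_outside
  coords <- array(0, dim = c(n_frames, n_pts, 3L))
  for (f in seq_len(n_frames)) {
    centres <- matrix(stats::runif(3L * n_pairs, 0.25 * box, 0.75 * box),
                      n_pairs, 3L)
    # random 3D orientations: normalised Gaussian vectors
    u <- matrix(stats::rnorm(3L * n_pairs), n_pairs, 3L)
    u <- u / sqrt(rowSums(u^2))
    pts <- rbind(centres - u * distance / 2, centres + u * distance / 2)
    if (jitter_sigma > 0)
      pts <- pts + stats::rnorm(length(pts), sd = jitter_sigma)
    if (n_outside > 0)
      pts <- rbind(pts, matrix(stats::runif(3L * n_outside, 0, box),
                               n_outside, 3L))
    coords[f, , ] <- pts
  }
  traj <- trajectory(coords, box = rep(box, 3L), dt = 1, wrapped = FALSE)
  groups <- group_spec(additives = seq_len(n_pts), n_particles = n_pts)
  list(trajectory = traj, groups = groups)
}

#' Tilted backbone rods
#'
#' Each frame holds one three-point backbone (end A, central ring,
#' end B): arm A tilted `alpha1` degrees from the +z bilayer normal, arm
#' B tilted `alpha2` degrees from -z, with Gaussian angular noise on the
#' polar angles. Azimuths are drawn at random per frame; with
#' `azimuth_offset` set, arm B's azimuth is locked to arm A's plus the
#' offset (0 gives a planar bent backbone whose bending angle is
#' `180 - alpha1 - alpha2`).
#'
#' @param alpha1,alpha2 arm tilt angles (degrees, in `[0, 180]`).
#' @param arm_length backbone half-length (Angstrom).
#' @param noise_sigma Gaussian polar-angle noise (degrees).
#' @param azimuth_offset fixed azimuth difference between arms (degrees),
#'   or `NULL` for independent random azimuths.
#' @param n_frames,box,seed frame count, cubic box length, seed.
#' @return `list(trajectory, groups)` with one additive molecule whose
#'   backbone roles point at atoms 1 (end A), 2 (ring) and 3 (end B);
#'   terminal roles are placeholders on the end atoms.
#' @export
gen_rod_frames <- function(alpha1 = 20, alpha2 = 30, arm_length = 15,
                           noise_sigma = 0, azimuth_offset = NULL,
                           n_frames = 100, box = 98, seed = 1) {
  for (a in c(alpha1, alpha2))
    if (a < 0 || a > 180) abort_validation("tilt angles must lie in [0, 180]")
  assert_scalar_number(arm_length, "arm_length", lower = 0, strict = TRUE)
  assert_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  set.seed(seed)
  coords <- array(0, dim = c(n_frames, 3L, 3L))
  centre <- c(box / 2, box / 2, box / 2)
  deg <- pi / 180
  for (f in seq_len(n_frames)) {
    a1 <- (alpha1 + stats::rnorm(1, sd = noise_sigma)) * deg
    a2 <- (alpha2 + stats::rnorm(1, sd = noise_sigma)) * deg
    phi1 <- stats::runif(1, 0, 2 * pi)
    phi2 <- if (is.null(azimuth_offset)) stats::runif(1, 0, 2 * pi)
            else phi1 + azimuth_offset * deg
    u1 <- c(sin(a1) * cos(phi1), sin(a1) * sin(phi1), cos(a1))
    u2 <- c(sin(a2) * cos(phi2), sin(a2) * sin(phi2), -cos(a2))
    coords[f, 1, ] <- centre + arm_length * u1
    coords[f, 2, ] <- centre
    coords[f, 3, ] <- centre + arm_length * u2
  }
  traj <- trajectory(coords, box = rep(box, 3L), dt = 1, wrapped = FALSE)
  groups <- group_spec(
    additives = 1:3,
    molecules = list(list(backbone_end_a = 1L, backbone_end_b = 3L,
                          cor_ring_atoms = 2L, ch3_terminal = 1L,
                          cf3_terminal = 3L)),
    n_particles = 3L)
  list(trajectory = traj, groups = groups)
}

#' Bilayer slab with headgroup planes
#'
#' Headgroup markers sit at `z = +/- thickness/2` with Gaussian roughness
#' and uniform lateral placement; z = 0 is the bilayer centre. Optional
#' terminal-group particles draw their z from a user-supplied Gaussian
#' mixture, emulating the axial distributions of side-chain terminal
#' groups. Defaults reproduce the study bilayer: 40 Angstrom headgroup
#' separation, 144 lipids per leaflet.
#'
#' @param thickness headgroup plane separation (Angstrom).
#' @param roughness_sigma Gaussian z roughness (Angstrom).
#' @param n_per_leaflet headgroup markers per leaflet.
#' @param terminal_mixture optional list of components, each
#'   `list(mean =, sigma =, weight =)`, for terminal-particle z values.
#' @param n_terminals terminal particles per frame.
#' @param n_frames,lateral_box,box_z,seed frame count, lateral box,
#'   box height, seed.
#' @return `list(trajectory, groups)`: `headgroup_atoms`/`lipids` index
#'   the markers, `additives` the terminal particles.
#' @export
gen_bilayer_slab <- function(thickness = 40, roughness_sigma = 0,
                             n_per_leaflet = 144, terminal_mixture = NULL,
                             n_terminals = 0, n_frames = 100,
                             lateral_box = 98, box_z = 68, seed = 1) {
  assert_scalar_number(thickness, "thickness", lower = 0, strict = TRUE)
  assert_scalar_number(roughness_sigma, "roughness_sigma", lower = 0)
  set.seed(seed)
  n_head <- 2L * n_per_leaflet
  n_pts <- n_head + n_terminals
  coords <- array(0, dim = c(n_frames, n_pts, 3L))
  z_base <- rep(c(thickness / 2, -thickness / 2), each = n_per_leaflet)
  for (f in seq_len(n_frames)) {
    coords[f, , 1:2] <- stats::runif(n_pts * 2L, 0, lateral_box)
    z <- z_base
    if (roughness_sigma > 0) z <- z + stats::rnorm(n_head, sd = roughness_sigma)
    coords[f, seq_len(n_head), 3] <- z
    if (n_terminals > 0) {
      comp_w <- vapply(terminal_mixture, `[[`, numeric(1), "weight")
      comp <- sample.int(length(terminal_mixture), n_terminals,
                         replace = TRUE, prob = comp_w)
      mu <- vapply(terminal_mixture, `[[`, numeric(1), "mean")[comp]
      sg <- vapply(terminal_mixture, `[[`, numeric(1), "sigma")[comp]
      coords[f, (n_head + 1L):n_pts, 3] <- stats::rnorm(n_terminals, mu, sg)
    }
  }
  traj <- trajectory(coords, box = c(lateral_box, lateral_box, box_z),
                     dt = 1, wrapped = FALSE)
  add_idx <- if (n_terminals > 0) (n_head + 1L):n_pts else integer()
  groups <- group_spec(lipids = seq_len(n_head), additives = add_idx,
                       headgroup_atoms = seq_len(n_head),
                       n_particles = n_pts)
  list(trajectory = traj, groups = groups)
}

#' Two-state telegraph process
#'
#' Discrete-time two-state Markov chain (0/1) with stationary occupancy
#' `p_on` and an exactly exponential autocorrelation,
#' `corr(lag) = exp(-lag * dt / tau)`, started from stationarity. `tau`
#' is the autocorrelation e-folding time — the "characteristic time" the
#' cluster-kinetics estimator recovers. Emulates the presence/absence
#' indicator of a transient, recurrent additive trimer.
#'
#' @param tau relaxation time (ns).
#' @param p_on stationary probability of state 1, in (0, 1).
#' @param dt sampling interval (ns); must be `< tau`.
#' @param n_steps series length.
#' @param seed RNG seed.
#' @return data frame with columns `time` (ns) and `state` (0/1);
#'   attributes `tau`, `p_on`, `dt` record the ground truth.
#' @export
gen_telegraph <- function(tau = 100, p_on = 0.5, dt = 0.1,
                          n_steps = 1e6, seed = 1) {
  assert_scalar_number(tau, "tau", lower = 0, strict = TRUE)
  if (p_on <= 0 || p_on >= 1) abort_validation("'p_on' must lie in (0, 1)")
  if (dt >= tau)
    abort_validation("dt >= tau: chain would be undersampled")
  set.seed(seed)
  lam <- exp(-dt / tau)
  # per-step switch probabilities giving eigenvalue lam and occupancy p_on
  p_leave_on <- (1 - p_on) * (1 - lam)
  p_leave_off <- p_on * (1 - lam)
  s <- as.integer(stats::runif(1) < p_on)
  leave_p <- c(p_leave_off, p_leave_on)
  # alternating geometric dwell lengths; memoryless, so the stationary
  # start is exact. Each batch holds an even number of dwells, so the
  # alternation resumes from the same state if another batch is needed.
  n_draw <- max(64L, ceiling(n_steps * mean(leave_p)))
  seq_states <- integer(0)
  seq_dwell <- integer(0)
  while (sum(seq_dwell) < n_steps) {
    d_a <- 1L + stats::rgeom(n_draw, leave_p[s + 1L])
    d_b <- 1L + stats::rgeom(n_draw, leave_p[2L - s])
    seq_dwell <- c(seq_dwell, as.vector(rbind(d_a, d_b)))
    seq_states <- c(seq_states, rep_len(c(s, 1L - s), 2L * n_draw))
  }
  state <- rep(seq_states, seq_dwell)[seq_len(n_steps)]
  out <- data.frame(time = (seq_len(n_steps) - 1) * dt, state = state)
  attr(out, "tau") <- tau
  attr(out, "p_on") <- p_on
  attr(out, "dt") <- dt
  out
}
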