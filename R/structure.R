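#' Orientation and axial structure observables
#'
#' Backbone tilt and bending angles of the trans-bilayer additives,
#' side-chain orientation angles, axial (z) density profiles, bilayer
#' thickness, midplane occupancy and side-chain flip events. The bilayer
#' normal is the +z axis (planar-bilayer convention); z = 0 is the
#' bilayer centre for profiles.
#'
#' Angle conventions: `alpha1` and `alpha2` are the angles of the two
#' half-backbone vectors (end A - ring centre, end B - ring centre)
#' against +z, and `beta` is the angle between the two half-backbone
#' vectors, so a straight trans-bilayer backbone gives
#' `alpha1 = 0, alpha2 = 180, beta = 180` (180 deg = unbent).
#'
#' @name structure_observables
NULL

#' Backbone tilt and bending angles
#'
#' For each additive molecule and frame, computes the angles of the two
#' half-backbone vectors against the bilayer normal and the bending
#' angle between them. Both vectors are taken minimum-image.
#'
#' @param traj a `Trajectory`.
#' @param groups a `GroupSpec` with backbone roles.
#' @param normal bilayer normal (default `+z`).
#' @param weighted mass-weight the ring centroid.
#' @return data frame with columns `frame`, `molecule`, `alpha1`,
#'   `alpha2`, `beta` (degrees).
#' @export
backbone_angles <- function(traj, groups, normal = c(0, 0, 1),
                            weighted = TRUE) {
  stopifnot(inherits(traj, "Trajectory"), inherits(groups, "GroupSpec"))
  validate_group_spec(groups, traj$n_particles)
  if (length(groups$molecules) == 0L)
    abort_validation("group spec defines no additive molecules")
  normal <- normal / sqrt(sum(normal^2))
  cor <- cor_positions(traj, groups, weighted = weighted)
  res <- list()
  for (i in seq_along(groups$molecules)) {
    mol <- groups$molecules[[i]]
    for (f in seq_len(traj$n_frames)) {
      box <- traj$box[f, ]
      v1 <- min_image(traj$coords[f, mol$backbone_end_a[1], ] - cor[f, i, ], box)[1, ]
      v2 <- min_image(traj$coords[f, mol$backbone_end_b[1], ] - cor[f, i, ], box)[1, ]
      res[[length(res) + 1L]] <- data.frame(
        frame = f, molecule = i,
        alpha1 = vec_angle_deg(v1, normal),
        alpha2 = vec_angle_deg(v2, normal),
        beta = vec_angle_deg(v1, v2))
    }
  }
  do.call(rbind, res)
}

#' Side-chain orientation angles
#'
#' Angle between the vector from a side-chain terminal group to the
#' centre of the molecule's phenylene ring and the bilayer normal, in
#' `[0, 180]` degrees: 90 degrees means the terminal group sits directly
#' between the leaflets in the bilayer plane.
#'
#' @param traj a `Trajectory`.
#' @param groups a `GroupSpec`.
#' @param terminal which terminal role to use, `"ch3"` or `"cf3"`.
#' @param normal bilayer normal (default `+z`).
#' @param weighted mass-weight the ring centroid.
#' @return data frame with columns `frame`, `molecule`, `angle` (degrees).
#' @export
side_chain_angle <- function(traj, groups, terminal = c("ch3", "cf3"),
                             normal = c(0, 0, 1), weighted = TRUE) {
  stopifnot(inherits(traj, "Trajectory"), inherits(groups, "GroupSpec"))
  terminal <- match.arg(terminal)
  role <- paste0(terminal, "_terminal")
  validate_group_spec(groups, traj$n_particles)
  normal <- normal / sqrt(sum(normal^2))
  cor <- cor_positions(traj, groups, weighted = weighted)
  res <- list()
  for (i in seq_along(groups$molecules)) {
    idx <- groups$molecules[[i]][[role]][1]
    for (f in seq_len(traj$n_frames)) {
      v <- min_image(cor[f, i, ] - traj$coords[f, idx, ], traj$box[f, ])[1, ]
      res[[length(res) + 1L]] <- data.frame(
        frame = f, molecule = i, angle = vec_angle_deg(v, normal))
    }
  }
  do.call(rbind, res)
}

#' Normalised angle histogram
#'
#' Probability density per degree over `[0, 180]`.
#'
#' @param values angles in degrees, all in `[0, 180]`.
#' @param bin_width bin width in degrees (default 2).
#' @return an object of class `"AngleDistribution"`: `bin_centers`,
#'   `density` (probability per degree).
#' @export
angle_histogram <- function(values, bin_width = 2) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0 | values > 180))
    abort_validation("angle values must lie in [0, 180] degrees")
  edges <- seq(0, 180, by = bin_width)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  counts <- tabulate(pmin(floor(values / bin_width) + 1L,
                          length(edges) - 1L), length(edges) - 1L)
  widths <- diff(edges)
  density <- counts / sum(counts) / widths
  structure(list(bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 density = density, bin_width = bin_width),
            class = "AngleDistribution")
}

#' Axial density profile
#'
#' Histogram of z positions of a particle group relative to the per-frame
#' COM z of a reference group (conventionally the whole system, so the
#' bilayer centre sits at z = 0), normalised to unit area. Bins are
#' symmetric about zero.
#'
#' @param traj a `Trajectory`.
#' @param group particle indices profiled.
#' @param reference reference group for the per-frame COM z.
#' @param bin_width bin width (Angstrom, default 1).
#' @param z_range half-range of the profile (Angstrom, default 34).
#' @param weighted mass-weight the reference COM.
#' @return an object of class `"DensityProfile"`: `z_bin_centers`,
#'   `density` (probability per Angstrom), `group_label`.
#' @export
z_profile <- function(traj, group, reference, bin_width = 1, z_range = 34,
                      weighted = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  group <- as.integer(group)
  if (length(group) == 0L) abort_validation("'group' is empty")
  com_z <- group_com(traj, reference, weighted = weighted)[, 3]
  z <- sweep(matrix(traj$coords[, group, 3], nrow = traj$n_frames), 1L, com_z)
  z <- as.numeric(z)
  # bins symmetric about 0: centres at 0, +/- bin_width, ...
  half_bins <- ceiling((z_range - bin_width / 2) / bin_width)
  edges <- seq(-(half_bins + 0.5) * bin_width, (half_bins + 0.5) * bin_width,
               by = bin_width)
  z <- z[z >= edges[1] & z < edges[length(edges)]]
  if (length(z) == 0L)
    abort_validation("no particles inside the profile range")
  counts <- tabulate(floor((z - edges[1]) / bin_width) + 1L,
                     length(edges) - 1L)
  density <- counts / sum(counts) / bin_width
  structure(list(z_bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 density = density, bin_width = bin_width,
                 group_label = paste0(length(group), " particles")),
            class = "DensityProfile")
}

#' Peak-to-peak bilayer thickness
#'
#' Distance between the density maxima of the upper and lower leaflet in
#' a headgroup z profile.
#'
#' @param profile a `DensityProfile` of headgroup markers.
#' @return thickness in Angstrom.
#' @export
bilayer_thickness <- function(profile) {
  stopifnot(inherits(profile, "DensityProfile"))
  up <- profile$z_bin_centers > 0
  lo <- profile$z_bin_centers < 0
  if (!any(profile$density[up] > 0) || !any(profile$density[lo] > 0))
    abort_validation("profile has no density on both sides of z = 0")
  z_up <- profile$z_bin_centers[up][which.max(profile$density[up])]
  z_lo <- profile$z_bin_centers[lo][which.max(profile$density[lo])]
  z_up - z_lo
}

#' Midplane occupancy ratio
#'
#' Mean density within `|z| <= center_halfwidth` divided by the global
#' maximum of the profile — the relative occurrence of a group at the
#' bilayer centre compared to its preferred location.
#'
#' @param profile a `DensityProfile`.
#' @param center_halfwidth half-width of the central band (Angstrom).
#' @return dimensionless ratio in `[0, 1]` for unimodal-peak profiles.
#' @export
midplane_ratio <- function(profile, center_halfwidth = 2) {
  stopifnot(inherits(profile, "DensityProfile"))
  centre <- abs(profile$z_bin_centers) <= center_halfwidth + 1e-9
  mean(profile$density[centre]) / max(profile$density)
}

#' Leaflet flip events of a terminal group
#'
#' Tracks a per-molecule terminal z series through the two leaflet bands
#' `z > +threshold` and `z < -threshold`. A flip is recorded when the
#' series enters the band opposite to the one it last occupied; transient
#' excursions into the midplane region that return to the same band are
#' not flips. Dwell time is the time between consecutive flips.
#'
#' @param z_series numeric vector of z positions over frames (Angstrom).
#' @param dt frame spacing (ns).
#' @param threshold band boundary (Angstrom, default 10).
#' @return list with `times` (ns of each flip), `dwell` (ns between
#'   consecutive flips) and `n_flips`.
#' @export
flip_events <- function(z_series, dt, threshold = 10) {
  assert_scalar_number(threshold, "threshold", lower = 0, strict = TRUE)
  band <- ifelse(z_series > threshold, 1L, ifelse(z_series < -threshold, -1L, 0L))
  times <- numeric(0)
  last <- 0L
  for (f in seq_along(band)) {
    if (band[f] == 0L) next
    if (last != 0L && band[f] != last) times <- c(times, (f - 1L) * dt)
    last <- band[f]
  }
  list(times = times,
       dwell = if (length(times) > 1L) diff(times) else numeric(0),
       n_flips = length(times))
}
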