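rod_groups <- function() {
  group_spec(additives = 1:3, molecules = list(list(
    backbone_end_a = 1L, backbone_end_b = 3L, cor_ring_atoms = 2L,
    ch3_terminal = 1L, cf3_terminal = 3L)), n_particles = 3)
}

test_that("backbone angles honour the stated conventions", {
  co <- array(0, dim = c(1, 3, 3))
  co[1, 2, ] <- c(50, 50, 50)
  co[1, 1, ] <- c(50, 50, 55)     # end A straight up
  co[1, 3, ] <- c(50, 50, 45)     # end B straight down
  ang <- backbone_angles(toy_traj(co), rod_groups())
  expect_equal(c(ang$alpha1, ang$alpha2, ang$beta), c(0, 180, 180),
               tolerance = 1e-9)

  co[1, 1, ] <- c(55, 50, 50)     # both arms in-plane, orthogonal
  co[1, 3, ] <- c(50, 55, 50)
  ang <- backbone_angles(toy_traj(co), rod_groups())
  expect_equal(c(ang$alpha1, ang$alpha2, ang$beta), c(90, 90, 90),
               tolerance = 1e-9)
})

test_that("backbone angles are invariant under z-rotation and translation", {
  rod <- gen_rod_frames(alpha1 = 25, alpha2 = 40, noise_sigma = 5,
                        n_frames = 20, seed = 19)
  a0 <- backbone_angles(rod$trajectory, rod$groups)
  th <- 1.1
  tr <- rod$trajectory
  x <- tr$coords[, , 1] - 49; y <- tr$coords[, , 2] - 49
  tr$coords[, , 1] <- cos(th) * x - sin(th) * y + 12
  tr$coords[, , 2] <- sin(th) * x + cos(th) * y - 3
  tr$coords[, , 3] <- tr$coords[, , 3] + 7
  a1 <- backbone_angles(tr, rod$groups)
  expect_equal(a1$alpha1, a0$alpha1, tolerance = 1e-9)
  expect_equal(a1$alpha2, a0$alpha2, tolerance = 1e-9)
  expect_equal(a1$beta, a0$beta, tolerance = 1e-9)
})

test_that("noise-free rods round-trip through measure and regenerate", {
  rod <- gen_rod_frames(alpha1 = 33, alpha2 = 61, azimuth_offset = 0,
                        noise_sigma = 0, n_frames = 5, seed = 2)
  ang <- backbone_angles(rod$trajectory, rod$groups)
  rod2 <- gen_rod_frames(alpha1 = ang$alpha1[1],
                         alpha2 = 180 - ang$alpha2[1],
                         azimuth_offset = 0, noise_sigma = 0,
                         n_frames = 5, seed = 2)
  ang2 <- backbone_angles(rod2$trajectory, rod2$groups)
  expect_equal(ang2$alpha1, ang$alpha1, tolerance = 1e-9)
  expect_equal(ang2$alpha2, ang$alpha2, tolerance = 1e-9)
  expect_equal(ang2$beta, ang$beta, tolerance = 1e-9)
})

test_that("side-chain angle measures terminal-to-ring orientation", {
  co <- array(0, dim = c(1, 3, 3))
  co[1, 2, ] <- c(50, 50, 50)
  co[1, 1, ] <- c(50, 50, 45)     # ch3 terminal directly below the ring
  co[1, 3, ] <- c(55, 50, 50)     # cf3 terminal purely lateral
  tr <- toy_traj(co)
  expect_equal(side_chain_angle(tr, rod_groups(), "ch3")$angle, 0,
               tolerance = 1e-9)
  expect_equal(side_chain_angle(tr, rod_groups(), "cf3")$angle, 90,
               tolerance = 1e-9)
  co[1, 1, ] <- c(50, 50, 50) + c(3, 0, 3)  # vector to ring = -(1,0,1)
  expect_equal(side_chain_angle(toy_traj(co), rod_groups(), "ch3")$angle,
               135, tolerance = 1e-9)
})

test_that("angle histograms are normalised probability densities", {
  h <- angle_histogram(rep(90, 50), bin_width = 2)
  expect_equal(sum(h$density * 2), 1, tolerance = 1e-9)
  expect_equal(sum(h$density > 0), 1L)
  expect_equal(h$bin_centers[which(h$density > 0)], 91)

  set.seed(5)
  u <- stats::runif(20000, 0, 180)
  hu <- angle_histogram(u, bin_width = 5)
  expect_equal(sum(hu$density * 5), 1, tolerance = 1e-9)
  expect_lt(max(abs(hu$density - 1 / 180)), 3 * sqrt(1 / (20000 * 5 * 180)))

  # normalisation holds for any input size >= 1
  for (n in c(1, 3, 17)) {
    h <- angle_histogram(stats::runif(n, 0, 180), bin_width = 2)
    expect_equal(sum(h$density * 2), 1, tolerance = 1e-9)
  }
  expect_error(angle_histogram(c(10, 190)), "0, 180")
})

test_that("noisy rod tilt distribution recovers the generator mean", {
  rod <- gen_rod_frames(alpha1 = 30, alpha2 = 30, noise_sigma = 5,
                        n_frames = 400, seed = 23)
  ang <- backbone_angles(rod$trajectory, rod$groups)
  se <- 5 / sqrt(400)
  expect_lt(abs(mean(ang$alpha1) - 30), 3 * se)
  h <- angle_histogram(ang$alpha1, bin_width = 2)
  mu <- sum(h$bin_centers * h$density * 2)
  expect_lt(abs(mu - 30), 3 * se + 1)   # binning adds < one bin of slack
})

test_that("z profiles localise groups relative to the reference COM", {
  # all particles at the reference COM z: delta at 0
  co <- array(2, dim = c(3, 4, 3))
  tr <- toy_traj(co)
  prof <- z_profile(tr, 1:2, 1:4, bin_width = 1, z_range = 10)
  expect_equal(sum(prof$density * 1), 1, tolerance = 1e-9)
  expect_equal(prof$z_bin_centers[which(prof$density > 0)], 0)

  # slab headgroups at +-20: two delta bins
  slab <- gen_bilayer_slab(thickness = 40, roughness_sigma = 0,
                           n_per_leaflet = 20, n_frames = 5, seed = 1)
  all_idx <- seq_len(slab$trajectory$n_particles)
  prof <- z_profile(slab$trajectory, slab$groups$headgroup_atoms, all_idx)
  nz <- prof$z_bin_centers[prof$density > 0]
  expect_equal(sort(nz), c(-20, 20))

  # terminal mixture at the bilayer centre shows a central maximum
  slab2 <- gen_bilayer_slab(thickness = 40, roughness_sigma = 1,
                            n_per_leaflet = 30, n_terminals = 40,
                            terminal_mixture = list(
                              list(mean = 0, sigma = 2, weight = 1)),
                            n_frames = 50, seed = 2)
  prof2 <- z_profile(slab2$trajectory, slab2$groups$additives,
                     seq_len(slab2$trajectory$n_particles))
  expect_equal(prof2$z_bin_centers[which.max(prof2$density)], 0,
               tolerance = 1.01)
})

test_that("z profile is invariant to collective drift", {
  slab <- gen_bilayer_slab(thickness = 30, roughness_sigma = 1,
                           n_per_leaflet = 10, n_frames = 10, seed = 3)
  tr <- slab$trajectory
  all_idx <- seq_len(tr$n_particles)
  p0 <- z_profile(tr, slab$groups$headgroup_atoms, all_idx)
  drifted <- tr
  drifted$coords[, , 3] <- tr$coords[, , 3] + cumsum(rep(0.7, tr$n_frames))
  p1 <- z_profile(drifted, slab$groups$headgroup_atoms, all_idx)
  expect_equal(p1$density, p0$density, tolerance = 1e-12)
})

test_that("bilayer thickness is the peak-to-peak headgroup distance", {
  mk_prof <- function(z_up, z_lo) {
    z <- seq(-30.5, 30.5, by = 1)
    centers <- (z[-1] + z[-length(z)]) / 2
    d <- numeric(length(centers))
    d[which.min(abs(centers - z_up))] <- 0.5
    d[which.min(abs(centers - z_lo))] <- 0.5
    structure(list(z_bin_centers = centers, density = d, bin_width = 1,
                   group_label = "hg"), class = "DensityProfile")
  }
  expect_equal(bilayer_thickness(mk_prof(20, -20)), 40)
  expect_equal(bilayer_thickness(mk_prof(17.5, -17.5)), 35)
  one_sided <- mk_prof(20, -20)
  one_sided$density[one_sided$z_bin_centers < 0] <- 0
  expect_error(bilayer_thickness(one_sided), "both sides")
})

test_that("midplane ratio reads the central occupancy", {
  z <- seq(-30.5, 30.5, by = 1)
  centers <- (z[-1] + z[-length(z)]) / 2
  flat <- structure(list(z_bin_centers = centers,
                         density = rep(1 / 61, 61), bin_width = 1,
                         group_label = "x"), class = "DensityProfile")
  expect_equal(midplane_ratio(flat), 1.0, tolerance = 1e-12)

  d <- rep(0, 61); d[abs(centers) > 25] <- 0.09
  hollow <- flat; hollow$density <- d
  expect_equal(midplane_ratio(hollow), 0)

  # central plateau at one ninth of the peak
  d <- rep(0, 61)
  d[which.min(abs(centers - 20))] <- 0.9
  d[which.min(abs(centers + 20))] <- 0.9
  d[abs(centers) <= 2] <- 0.1
  ninth <- flat; ninth$density <- d
  expect_equal(midplane_ratio(ninth, center_halfwidth = 2), 1 / 9,
               tolerance = 1e-9)
})

test_that("flip events count band-to-band crossings only", {
  expect_equal(flip_events(rep(15, 100), dt = 0.1)$n_flips, 0L)

  z <- c(rep(15, 10), rep(-15, 10))
  ev <- flip_events(z, dt = 0.1)
  expect_equal(ev$n_flips, 1L)
  expect_equal(ev$times, 10 * 0.1)

  # an excursion to the midplane that returns is not a flip
  z2 <- c(rep(15, 5), rep(0, 5), rep(15, 5), rep(-15, 5))
  expect_equal(flip_events(z2, dt = 1)$n_flips, 1L)
})

test_that("telegraph-driven flips recover the generator dwell time", {
  tg <- gen_telegraph(tau = 1, p_on = 0.5, dt = 0.01, n_steps = 5e4,
                      seed = 31)
  z <- ifelse(tg$state == 1, 15, -15)
  ev <- flip_events(z, dt = 0.01)
  runs <- rle(tg$state)
  gen_dwell <- mean(runs$lengths) * 0.01
  se <- stats::sd(ev$dwell) / sqrt(length(ev$dwell))
  expect_lt(abs(mean(ev$dwell) - gen_dwell), 3 * se + 0.05 * gen_dwell)
})
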