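test_that("adjacency follows the distance cutoff under minimum image", {
  pts <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4.33, 0))
  adj <- build_adjacency(pts, box = rep(100, 3), cutoff = 9.5)
  expect_true(all(adj[upper.tri(adj)]))
  expect_false(any(diag(adj)))

  far <- rbind(c(0, 0, 0), c(20, 0, 0))
  expect_false(any(build_adjacency(far, box = rep(100, 3), cutoff = 9.5)))

  # periodic wrap: points near opposite faces are adjacent
  edge <- rbind(c(1, 0, 0), c(99, 0, 0))
  expect_true(build_adjacency(edge, box = rep(100, 3), cutoff = 5)[1, 2])

  # brute-force oracle on random points
  set.seed(43)
  for (rep in 1:5) {
    p <- matrix(stats::runif(10 * 3, 0, 30), 10, 3)
    adj <- build_adjacency(p, box = rep(30, 3), cutoff = 8, mode = "3d")
    for (i in 1:9) for (j in (i + 1):10) {
      d <- p[i, ] - p[j, ]
      d <- d - 30 * round(d / 30)
      expect_equal(adj[i, j], sqrt(sum(d^2)) <= 8)
    }
  }
})

test_that("connected components match exhaustive reachability", {
  # chain a-b, b-c is one component
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  expect_equal(connected_components(adj), c(1L, 1L, 1L))

  # no edges: all singletons
  expect_equal(connected_components(matrix(FALSE, 6, 6)), 1:6)

  set.seed(47)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    adj <- matrix(stats::runif(n * n) < 0.3, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    got <- connected_components(adj)
    want <- brute_components(adj)
    # same partition (labels both ordered by lowest member)
    expect_identical(got, want)
  }
})

test_that("cluster labels are invariant under reordering and translation", {
  set.seed(53)
  p <- matrix(stats::runif(8 * 3, 0, 40), 8, 3)
  lab0 <- connected_components(build_adjacency(p, rep(40, 3), 9))
  shifted <- sweep(p, 2, c(5, -3, 2), "+") %% 40
  lab1 <- connected_components(build_adjacency(shifted, rep(40, 3), 9))
  expect_identical(lab1, lab0)
  perm <- sample(8)
  lab2 <- connected_components(build_adjacency(p[perm, ], rep(40, 3), 9))
  # same partition up to relabeling
  expect_equal(length(unique(lab2)), length(unique(lab0)))
  expect_true(all(table(lab2) %in% table(lab0)))
})

test_that("enlarging the cutoff never increases the component count", {
  set.seed(59)
  p <- matrix(stats::runif(10 * 3, 0, 50), 10, 3)
  cuts <- c(2, 5, 8, 12, 20, 40)
  ncomp <- vapply(cuts, function(cc)
    length(unique(connected_components(
      build_adjacency(p, rep(50, 3), cc, mode = "3d")))), integer(1))
  expect_true(all(diff(ncomp) <= 0))
})

test_that("cluster timeseries flags trimers per frame", {
  out <- gen_cluster_frames(jitter_sigma = 0.2, n_outside = 3,
                            min_separation = 15, n_frames = 30, seed = 61)
  cts <- cluster_timeseries(out$trajectory, out$groups, cutoff = 9.5)
  expect_true(all(cts$trimer_indicator == 1L))
  for (f in 1:30) expect_equal(cts$sizes[[f]], c(3L, 1L, 1L, 1L))
  # labels partition the molecules
  expect_true(all(rowSums(!is.na(cts$labels)) == 6))

  # all far apart: all singletons
  far <- gen_cluster_frames(pair_distance = 30, third_distance = 45,
                            jitter_sigma = 0, n_outside = 0,
                            n_frames = 5, box = 200, seed = 2)
  cts2 <- cluster_timeseries(far$trajectory, far$groups, cutoff = 9.5)
  expect_true(all(cts2$trimer_indicator == 0L))

  # alternating clustered/dispersed frames alternate the indicator
  close3 <- gen_cluster_frames(jitter_sigma = 0, n_outside = 0,
                               n_frames = 2, seed = 3)$trajectory$coords[1, , ]
  co <- array(0, dim = c(4, 3, 3))
  spread <- rbind(c(0, 0, 34), c(40, 40, 34), c(80, 10, 34))
  co[1, , ] <- close3; co[3, , ] <- close3
  co[2, , ] <- spread; co[4, , ] <- spread
  tr <- toy_traj(co, box = c(98, 98, 98))
  grp <- group_spec(additives = 1:3, molecules = lapply(1:3, function(i)
    stats::setNames(rep(list(i), 5),
                    c("backbone_end_a", "backbone_end_b", "cor_ring_atoms",
                      "ch3_terminal", "cf3_terminal"))), n_particles = 3)
  cts3 <- cluster_timeseries(tr, grp, cutoff = 9.5)
  expect_equal(cts3$trimer_indicator, c(1L, 0L, 1L, 0L))
})

test_that("membership exchange is detected between consecutive trimer frames", {
  co <- array(0, dim = c(3, 4, 3))
  tight <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4, 0))
  co[1, 1:3, ] <- tight; co[1, 4, ] <- c(50, 50, 0)
  co[2, 1:3, ] <- tight; co[2, 4, ] <- c(50, 50, 0)
  co[3, 2:4, ] <- tight; co[3, 1, ] <- c(50, 50, 0)   # molecule 1 swapped for 4
  tr <- toy_traj(co, box = c(98, 98, 98))
  grp <- group_spec(additives = 1:4, molecules = lapply(1:4, function(i)
    stats::setNames(rep(list(i), 5),
                    c("backbone_end_a", "backbone_end_b", "cor_ring_atoms",
                      "ch3_terminal", "cf3_terminal"))), n_particles = 4)
  cts <- cluster_timeseries(tr, grp, cutoff = 9.5)
  ev <- exchange_events(cts)
  expect_equal(ev$n_exchanges, 1L)
})

test_that("e-folding estimator is exact on an exponential curve", {
  dt <- 0.1
  for (tau in c(3, 10, 47)) {
    rho <- exp(-(0:5000) * dt / tau)
    expect_lt(abs(bilayerlab:::efolding_time(rho, dt) - tau) / tau, 0.01)
  }
})

test_that("characteristic timescale recovers telegraph ground truth", {
  expect_error(characteristic_timescale(rep(1, 100), dt = 0.1), "constant")

  # strictly periodic indicator: crossing well below P/4
  per <- rep(c(rep(1, 50), rep(0, 50)), 20)
  est <- characteristic_timescale(per, dt = 0.1, max_lag = 20)
  expect_lt(est$tau, 100 * 0.1 / 4)

  tg <- gen_telegraph(tau = 10, p_on = 0.5, dt = 0.1, n_steps = 2e5,
                      seed = 67)
  est <- characteristic_timescale(tg$state, dt = 0.1, max_lag = 100)
  expect_lt(abs(est$tau - 10) / 10, 0.15)
  expect_equal(est$stationary_fraction, mean(tg$state))

  # recovery across seeds (median within 15%)
  taus <- vapply(1:10, function(s) {
    x <- gen_telegraph(tau = 10, p_on = 0.5, dt = 0.1, n_steps = 1e5,
                       seed = 100 + s)
    characteristic_timescale(x$state, dt = 0.1, max_lag = 80)$tau
  }, numeric(1))
  expect_lt(abs(stats::median(taus) - 10) / 10, 0.15)
})
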