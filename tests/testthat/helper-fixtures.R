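# Shared fixtures and independent brute-force oracles.

# small trajectory with given coordinate array defaults
toy_traj <- function(coords, box = c(100, 100, 100), dt = 1,
                     wrapped = FALSE, masses = NULL) {
  trajectory(coords, box = box, dt = dt, wrapped = wrapped, masses = masses)
}

random_traj <- function(n_frames, n_particles, seed = 1, box = c(100, 100, 100),
                        sd = 1) {
  set.seed(seed)
  co <- array(stats::rnorm(n_frames * n_particles * 3, sd = sd),
              dim = c(n_frames, n_particles, 3))
  toy_traj(co, box = box)
}

# brute-force MSD: explicit double loop over origins and lags
brute_msd <- function(coords, group, max_m, dims = 1:2, stride = 1L) {
  n <- dim(coords)[1]
  out <- numeric(max_m + 1L)
  for (m in 0:max_m) {
    vals <- c()
    for (t0 in seq(1L, n - m, by = stride)) {
      for (i in group) {
        d <- coords[t0 + m, i, dims] - coords[t0, i, dims]
        vals <- c(vals, sum(d^2))
      }
    }
    out[m + 1L] <- mean(vals)
  }
  out
}

# brute-force minimum-image pair distance histogram counts (same set)
brute_pair_counts <- function(pts, box, edges, dims = 1:3) {
  n <- nrow(pts)
  counts <- numeric(length(edges) - 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pts[i, dims] - pts[j, dims]
      d <- d - box[dims] * round(d / box[dims])
      r <- sqrt(sum(d^2))
      k <- findInterval(r, edges, rightmost.closed = FALSE)
      if (k >= 1 && k <= length(counts) && r < edges[length(edges)])
        counts[k] <- counts[k] + 1
    }
  }
  counts
}

# exhaustive reachability closure for component labelling, n small
brute_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  labels <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      nxt <- nxt + 1L
      labels[which(reach[i, ])] <- nxt
    }
  }
  labels
}

# synthetic RDFResult from an analytic curve, for peak-detection oracles
fake_rdf <- function(r, g, mode = "lateral") {
  structure(list(bin_centers = r, g = g, counts = g, mode = mode,
                 n_frames_used = 1L, reference_density = 1,
                 dr = r[2] - r[1]),
            class = "RDFResult")
}
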