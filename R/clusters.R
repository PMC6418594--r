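#' Transient cluster detection and kinetics
#'
#' Additive molecules are clustered frame by frame with a first-shell
#' distance criterion on their COR positions: two molecules are adjacent
#' when their minimum-image (lateral by default) distance is within a
#' cutoff, and clusters are the connected components of that graph. The
#' per-frame trimer indicator (any component of size >= 3) is a two-state
#' process whose characteristic time is estimated from its
#' autocorrelation e-folding.
#'
#' @name cluster_analysis
NULL

#' Distance-cutoff adjacency of molecular centres
#'
#' @param points `n x 3` matrix of per-molecule coordinates in one frame.
#' @param box orthorhombic box lengths.
#' @param cutoff adjacency distance (Angstrom).
#' @param mode `"lateral"` (xy distances) or `"3d"`.
#' @return symmetric logical `n x n` matrix with `FALSE` diagonal.
#' @export
build_adjacency <- function(points, box, cutoff,
                            mode = c("lateral", "3d")) {
  mode <- match.arg(mode)
  assert_scalar_number(cutoff, "cutoff", lower = 0, strict = TRUE)
  points <- as.matrix(points)
  n <- nrow(points)
  dims <- if (mode == "lateral") 1:2 else 1:3
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- min_image(points[(i + 1L):n, dims, drop = FALSE] -
                       matrix(points[i, dims], n - i, length(dims), byrow = TRUE),
                     box[dims])
      hit <- sqrt(rowSums(d^2)) <= cutoff
      adj[i, (i + 1L):n] <- hit
      adj[(i + 1L):n, i] <- hit
    }
  }
  adj
}

#' Connected components of an adjacency matrix
#'
#' Components are labelled deterministically by their lowest member
#' index (label 1 contains molecule 1, and so on).
#'
#' @param adj symmetric logical adjacency matrix.
#' @return integer component label per molecule.
#' @export
connected_components <- function(adj) {
  n <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  # relabel so components are numbered by lowest member index
  first <- tapply(seq_len(n), memb, min)
  order_map <- match(memb, memb[sort(first)])
  as.integer(order_map)
}

#' Per-frame cluster labels, sizes and trimer indicator
#'
#' @param traj a `Trajectory`.
#' @param groups a `GroupSpec` defining the additive molecules.
#' @param cutoff adjacency cutoff (Angstrom); the conventional default is
#'   the first minimum of the COR-COR g(r), with 9.5 A (midway between
#'   the nearest- and second-neighbour shells) as fallback.
#' @param mode `"lateral"` or `"3d"`.
#' @param weighted mass-weight the ring centroids.
#' @return an object of class `"ClusterTimeseries"`: `labels`
#'   (`n_frames x n_molecules` integer matrix), `sizes` (list of size
#'   multisets per frame), `trimer_indicator` (0/1 per frame),
#'   `cutoff_used`, `dt`.
#' @export
cluster_timeseries <- function(traj, groups, cutoff = 9.5,
                               mode = c("lateral", "3d"),
                               weighted = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "Trajectory"), inherits(groups, "GroupSpec"))
  n_mol <- length(groups$molecules)
  if (n_mol < 2L)
    abort_validation("cluster analysis needs at least 2 additive molecules")
  cor <- cor_positions(traj, groups, weighted = weighted)
  labels <- matrix(NA_integer_, traj$n_frames, n_mol)
  indicator <- integer(traj$n_frames)
  sizes <- vector("list", traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    adj <- build_adjacency(matrix(cor[f, , ], ncol = 3L), traj$box[f, ],
                           cutoff, mode)
    lab <- connected_components(adj)
    labels[f, ] <- lab
    sz <- as.integer(table(lab))
    sizes[[f]] <- sort(sz, decreasing = TRUE)
    indicator[f] <- as.integer(any(sz >= 3L))
  }
  structure(list(labels = labels, sizes = sizes,
                 trimer_indicator = indicator, cutoff_used = cutoff,
                 mode = mode, dt = traj$dt),
            class = "ClusterTimeseries")
}

#' @export
print.ClusterTimeseries <- function(x, ...) {
  cat(sprintf(
    "<ClusterTimeseries> %d frames, %d molecules, cutoff %.2f A (%s), trimer fraction %.2f\n",
    nrow(x$labels), ncol(x$labels), x$cutoff_used, x$mode,
    mean(x$trimer_indicator)))
  invisible(x)
}

#' Membership exchange events of the largest cluster
#'
#' Counts frames (among consecutive frame pairs in which the trimer
#' indicator stays 1) where the membership set of the largest size->=3
#' component changes — the molecules of the transient cluster being
#' swapped over time.
#'
#' @param cts a `ClusterTimeseries`.
#' @return list with `n_exchanges` and `exchange_times` (ns).
#' @export
exchange_events <- function(cts) {
  stopifnot(inherits(cts, "ClusterTimeseries"))
  members <- function(f) {
    lab <- cts$labels[f, ]
    tab <- table(lab)
    big <- names(tab)[tab >= 3L]
    if (length(big) == 0L) return(NULL)
    # largest (ties: lowest label)
    sel <- big[which.max(tab[big])]
    which(lab == as.integer(sel))
  }
  times <- numeric(0)
  for (f in seq_len(nrow(cts$labels) - 1L)) {
    if (cts$trimer_indicator[f] == 1L && cts$trimer_indicator[f + 1L] == 1L) {
      m1 <- members(f); m2 <- members(f + 1L)
      if (!is.null(m1) && !is.null(m2) && !setequal(m1, m2))
        times <- c(times, f * cts$dt)
    }
  }
  list(n_exchanges = length(times), exchange_times = times)
}

# First crossing of 1/e of a normalised autocorrelation curve
# rho[k+1] = correlation at lag k*dt, with linear interpolation between
# the bracketing lags.
efolding_time <- function(rho, dt) {
  thr <- exp(-1)
  below <- which(rho < thr)
  if (length(below) == 0L) {
    warning("autocorrelation never falls below 1/e within max_lag; ",
            "increase max_lag or the series length", call. = FALSE)
    return((length(rho) - 1L) * dt)
  }
  i <- below[1]                        # 1-based index: lag = (i-1)*dt
  hi <- rho[i - 1L]; lo <- rho[i]
  frac <- (hi - thr) / (hi - lo)
  ((i - 2L) + frac) * dt
}

#' Characteristic timescale of a two-state indicator
#'
#' Normalised autocovariance of the indicator computed to `max_lag`; the
#' characteristic time is the lag at which it first falls below 1/e,
#' linearly interpolated between the bracketing lags. Mean on/off dwell
#' times are reported as secondary outputs.
#'
#' @param indicator binary series (0/1 per frame).
#' @param dt frame spacing (ns).
#' @param max_lag largest lag considered (ns).
#' @return an object of class `"TimescaleEstimate"`: `tau` (ns),
#'   `method`, `n_frames_used`, `stationary_fraction`, `mean_dwell_on`,
#'   `mean_dwell_off` (ns).
#' @export
characteristic_timescale <- function(indicator, dt, max_lag = NULL) {
  indicator <- as.numeric(indicator)
  n <- length(indicator)
  assert_scalar_number(dt, "dt", lower = 0, strict = TRUE)
  if (stats::var(indicator) == 0)
    abort_validation("indicator series is constant: timescale undefined")
  max_lag <- max_lag %||% ((n - 1) * dt / 4)
  max_m <- min(n - 1L, floor(max_lag / dt + 1e-9))
  ac <- autocorr_fft(indicator, max_m)
  rho <- ac / ac[1]
  tau <- efolding_time(rho, dt)
  runs <- rle(as.integer(indicator))
  if (n * dt < 10 * tau)
    warning("series shorter than 10x the estimated timescale; ",
            "estimate may be unreliable", call. = FALSE)
  structure(
    list(tau = tau, method = "autocorrelation e-folding",
         n_frames_used = n, stationary_fraction = mean(indicator),
         mean_dwell_on = mean(runs$lengths[runs$values == 1L]) * dt,
         mean_dwell_off = mean(runs$lengths[runs$values == 0L]) * dt),
    class = "TimescaleEstimate")
}

#' @export
print.TimescaleEstimate <- function(x, ...) {
  cat(sprintf(
    "<TimescaleEstimate> tau = %.3g ns (%s), on-fraction %.2f, %d frames\n",
    x$tau, x$method, x$stationary_fraction, x$n_frames_used))
  invisible(x)
}
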