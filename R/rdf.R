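#' Radial distribution functions
#'
#' g(r) is the probability of finding a pair of particles at separation r
#' relative to a completely random (ideal-gas) arrangement at the same
#' density. Distances use the minimum-image convention in the
#' orthorhombic cell. Two normalisations are available: `"3d"` (shell
#' volume `4 pi r^2 dr`, bulk density N/V) and `"lateral"` (xy distances
#' only, annulus area `2 pi r dr`, areal density N/A), the latter suited
#' to trans-bilayer molecules that share one z-band and cluster in-plane.
#'
#' @name pair_correlation
NULL

#' Molecular-centre (COR) positions of the additives
#'
#' Centroid of each additive's central phenylene ring atoms, per frame —
#' the molecule's positional marker for pair correlation and clustering.
#'
#' @param traj a `Trajectory`.
#' @param groups a `GroupSpec` whose molecules define `cor_ring_atoms`.
#' @param weighted mass-weight the centroid when masses are present.
#' @return numeric array `n_frames x n_molecules x 3` (Angstrom).
#' @export
cor_positions <- function(traj, groups, weighted = TRUE) {
  stopifnot(inherits(traj, "Trajectory"), inherits(groups, "GroupSpec"))
  if (length(groups$molecules) == 0L)
    abort_validation("group spec defines no additive molecules")
  validate_group_spec(groups, traj$n_particles)
  n_mol <- length(groups$molecules)
  out <- array(NA_real_, dim = c(traj$n_frames, n_mol, 3L))
  for (i in seq_len(n_mol)) {
    out[, i, ] <- group_com(traj, groups$molecules[[i]]$cor_ring_atoms,
                            weighted = weighted)
  }
  out
}

# Minimum-image pair distances between rows of a and b in one frame.
# When same_set = TRUE only unordered pairs i < j are returned.
frame_pair_distances <- function(a, b, box, dims, same_set,
                                 exclude = NULL) {
  na <- nrow(a); nb <- nrow(b)
  ii <- rep(seq_len(na), each = nb)
  jj <- rep(seq_len(nb), times = na)
  keep <- if (same_set) ii < jj else rep(TRUE, length(ii))
  if (!is.null(exclude)) keep <- keep & !(ii == jj)
  ii <- ii[keep]; jj <- jj[keep]
  d <- a[ii, dims, drop = FALSE] - b[jj, dims, drop = FALSE]
  d <- min_image(d, box[dims])
  sqrt(rowSums(d^2))
}

#' Pair correlation function g(r)
#'
#' Histograms minimum-image pair distances between two coordinate series
#' (or within one) and normalises by the ideal-gas expectation at the
#' same density, frame by frame. When `points_b` is omitted or identical
#' to `points_a`, self-pairs are excluded; with `exclude_same_index =
#' TRUE`, pairs with equal molecule index are excluded also across two
#' distinct series (used to drop intramolecular terminal contacts).
#'
#' @param points_a,points_b coordinate arrays `n_frames x n x 3`
#'   (e.g. from [cor_positions()]); `points_b = NULL` means `points_a`.
#' @param box orthorhombic box lengths, length-3 vector.
#' @param r_max histogram range (Angstrom); must not exceed half the
#'   smallest participating box length.
#' @param dr bin width (Angstrom), default 0.2.
#' @param mode `"lateral"` (xy only) or `"3d"`.
#' @param exclude_same_index drop equal-index cross pairs.
#' @return an object of class `"RDFResult"`: `bin_centers`, `g`,
#'   `counts`, `mode`, `n_frames_used`, `reference_density`.
#' @export
compute_rdf <- function(points_a, points_b = NULL, box, r_max = 30,
                        dr = 0.2, mode = c("lateral", "3d"),
                        exclude_same_index = FALSE) {
  mode <- match.arg(mode)
  assert_scalar_number(dr, "dr", lower = 0, strict = TRUE)
  if (length(dim(points_a)) != 3L)
    abort_validation("'points_a' must be an n_frames x n x 3 array")
  same_set <- is.null(points_b)
  if (same_set) points_b <- points_a
  dims <- if (mode == "lateral") 1:2 else 1:3
  half_min <- min(box[dims]) / 2
  if (r_max > half_min + 1e-9)
    abort_validation("r_max = %g exceeds half the smallest box length (%g)",
                     r_max, half_min)
  n_frames <- dim(points_a)[1]
  na <- dim(points_a)[2]; nb <- dim(points_b)[2]
  edges <- seq(0, r_max, by = dr)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  for (f in seq_len(n_frames)) {
    a <- matrix(points_a[f, , ], ncol = 3L)
    b <- matrix(points_b[f, , ], ncol = 3L)
    dist <- frame_pair_distances(a, b, box, dims, same_set,
                                 exclude = if (exclude_same_index) TRUE)
    dist <- dist[dist < r_max]
    if (length(dist))
      counts <- counts + tabulate(pmin(floor(dist / dr) + 1L, n_bins), n_bins)
  }
  measure <- if (mode == "lateral") prod(box[1:2]) else prod(box)
  n_pairs <- if (same_set) na * (na - 1) / 2
             else na * nb - if (exclude_same_index) min(na, nb) else 0
  r_lo <- edges[-length(edges)]; r_hi <- edges[-1]
  shell <- if (mode == "lateral") pi * (r_hi^2 - r_lo^2)
           else 4 / 3 * pi * (r_hi^3 - r_lo^3)
  ideal <- n_frames * n_pairs * shell / measure
  g <- ifelse(ideal > 0, counts / ideal, 0)
  structure(
    list(bin_centers = (r_lo + r_hi) / 2, g = g, counts = counts,
         ideal = ideal, mode = mode, n_frames_used = n_frames,
         reference_density = nb / measure, dr = dr),
    class = "RDFResult")
}

#' @export
print.RDFResult <- function(x, ...) {
  cat(sprintf("<RDFResult> %s, %d bins of %g A, %d frames, max g = %.3g\n",
              x$mode, length(x$g), x$dr, x$n_frames_used, max(x$g)))
  invisible(x)
}

moving_average <- function(y, window) {
  if (window <= 1L) return(y)
  half <- window %/% 2L
  n <- length(y)
  # edge-padded moving average keeps end bins comparable
  yp <- c(rep(y[1], half), y, rep(y[n], half))
  stats::filter(yp, rep(1 / window, window), sides = 2)[(half + 1L):(half + n)]
}

#' Detect peaks of a pair correlation function
#'
#' Smooths g(r) with a moving average, scans for local maxima and keeps
#' those whose prominence (height above the higher of the two flanking
#' minima towards taller neighbours or the curve ends) exceeds the
#' threshold. By default the threshold is relative — a fraction of the
#' smoothed curve's maximum — because the absolute scale of g(r) from a
#' sparse ensemble (a handful of molecules) is dominated by shell-volume
#' normalisation, and single-pair Poisson spikes at small r would
#' otherwise pass any fixed absolute cut.
#'
#' In addition, when the `RDFResult` carries raw pair counts and the
#' ideal-gas expectation per bin (as [compute_rdf()] output does), each
#' candidate peak must be statistically significant: the excess of
#' counts over the ideal-gas expectation, summed over the smoothing
#' window, must exceed `min_significance` Poisson standard deviations.
#' This rejects single-pair shot noise, which in a sparse system can
#' reach large g values at small r where the expected count per bin is
#' far below one, while true coordination shells accumulate counts
#' every frame.
#'
#' @param rdf an `RDFResult`.
#' @param smooth_window odd moving-average window in bins (default 5).
#' @param min_prominence minimum peak prominence (default 0.1).
#' @param relative interpret `min_prominence` as a fraction of the
#'   smoothed maximum (default `TRUE`); `FALSE` uses absolute g units.
#' @param min_significance minimum Poisson z of the windowed excess
#'   counts (default 5; 0 disables; skipped for curves constructed
#'   without count information).
#' @return an object of class `"PeakSet"`: `positions` (Angstrom,
#'   ascending), `heights`, `prominences`. May be empty.
#' @export
find_peaks <- function(rdf, smooth_window = 5L, min_prominence = 0.1,
                       relative = TRUE, min_significance = 5) {
  stopifnot(inherits(rdf, "RDFResult"))
  if (smooth_window %% 2L != 1L || smooth_window < 1L)
    abort_validation("'smooth_window' must be odd and >= 1")
  y <- as.numeric(moving_average(rdf$g, smooth_window))
  if (relative) min_prominence <- min_prominence * max(y)
  zsig <- NULL
  if (min_significance > 0 && !is.null(rdf$ideal) && !is.null(rdf$counts)) {
    wc <- as.numeric(moving_average(rdf$counts, smooth_window)) * smooth_window
    wi <- as.numeric(moving_average(rdf$ideal, smooth_window)) * smooth_window
    zsig <- (wc - wi) / sqrt(pmax(wi, 1e-12))
  }
  n <- length(y)
  is_max <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) y[i - 1L] else -Inf
    right <- if (i < n) y[i + 1L] else -Inf
    y[i] > left && y[i] >= right
  }, logical(1)))
  pos <- heights <- proms <- numeric(0)
  for (i in is_max) {
    # walk outwards to the nearest higher point (or the edge); the
    # prominence is the height above the larger of the two valley floors
    lmin <- y[i]; j <- i
    while (j > 1L && y[j - 1L] <= y[i]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    rmin <- y[i]; j <- i
    while (j < n && y[j + 1L] <= y[i]) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    prom <- y[i] - max(lmin, rmin)
    if (!is.null(zsig) && zsig[i] < min_significance) next
    if (prom >= min_prominence) {
      pos <- c(pos, rdf$bin_centers[i])
      heights <- c(heights, y[i])
      proms <- c(proms, prom)
    }
  }
  structure(list(positions = pos, heights = heights, prominences = proms,
                 smooth_window = smooth_window,
                 min_prominence = min_prominence),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  if (length(x$positions) == 0L) {
    cat("<PeakSet> no peaks\n")
  } else {
    cat(sprintf("<PeakSet> %d peak(s) at %s A\n", length(x$positions),
                paste(sprintf("%.2f", x$positions), collapse = ", ")))
  }
  invisible(x)
}

#' First minimum of g(r) after the first peak
#'
#' Position of the lowest smoothed g value between the first two detected
#' peaks (or, with a single peak, the first local minimum after it).
#' Supplies the first-coordination-shell cutoff used by the cluster
#' stage.
#'
#' @param rdf an `RDFResult`.
#' @param smooth_window,min_prominence forwarded to [find_peaks()].
#' @return position in Angstrom.
#' @export
first_minimum <- function(rdf, smooth_window = 5L, min_prominence = 0.1) {
  peaks <- find_peaks(rdf, smooth_window, min_prominence)
  if (length(peaks$positions) == 0L)
    abort_validation("no peaks detected: cannot locate a first minimum")
  y <- as.numeric(moving_average(rdf$g, smooth_window))
  i1 <- which.min(abs(rdf$bin_centers - peaks$positions[1]))
  if (length(peaks$positions) >= 2L) {
    i2 <- which.min(abs(rdf$bin_centers - peaks$positions[2]))
    seg <- i1:i2
    return(rdf$bin_centers[seg[which.min(y[seg])]])
  }
  for (i in (i1 + 1L):(length(y) - 1L)) {
    if (y[i] <= y[i - 1L] && y[i] < y[i + 1L]) return(rdf$bin_centers[i])
  }
  abort_validation("no local minimum found after the first peak")
}
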