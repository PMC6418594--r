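#' Mean squared displacement and lateral diffusion
#'
#' The lateral self-diffusion coefficient of a molecular group is
#' obtained from the multiple-time-origin mean squared displacement
#' MSD(t) = <|r(t0 + t) - r(t0)|^2> via the Einstein relation
#' D = slope / (2 d), with d = 2 for in-plane motion. Displacements are
#' measured after removing the collective motion of a reference group
#' (conventionally the lipid COM) so that drift of the whole phase does
#' not masquerade as diffusion.
#'
#' @name diffusion
NULL

# MSD of one scalar coordinate series for lags 0..max_m, all time
# origins, via the FFT autocorrelation identity
#   sum_t0 [x(t0+m)-x(t0)]^2 = S1(m) - 2*S2(m),
# with S1 from cumulative sums and S2 the (linear) autocorrelation.
msd_fft_1d <- function(x, max_m) {
  n <- length(x)
  mlen <- stats::nextn(2L * n, 2)
  fx <- stats::fft(c(x, rep(0, mlen - n)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(max_m + 1L)] / mlen
  d <- x^2
  ss <- sum(d)
  cs <- cumsum(d)
  m <- 0:max_m
  # sums of the first m and last m squared terms
  head_m <- c(0, cs)[m + 1L]
  tail_m <- ss - cs[n - m]
  s1 <- 2 * ss - head_m - tail_m
  (s1 - 2 * s2) / (n - m)
}

msd_direct <- function(xmat, max_m, stride) {
  # xmat: n_frames x n_coords; average over origins on `stride` and all
  # columns. Reference double-loop implementation.
  n <- nrow(xmat)
  out <- numeric(max_m + 1L)
  for (m in 0:max_m) {
    origins <- seq(1L, n - m, by = stride)
    acc <- 0
    for (t0 in origins) {
      acc <- acc + sum((xmat[t0 + m, ] - xmat[t0, ])^2)
    }
    out[m + 1L] <- acc / (length(origins) * ncol(xmat))
  }
  out
}

#' Multiple-time-origin mean squared displacement
#'
#' Removes the reference group's COM motion, then averages squared
#' displacements over all particles of `group` and all time origins (on
#' `origin_stride`) for every lag up to `max_lag`. With `lateral = TRUE`
#' only x and y enter, matching in-plane diffusion in a planar bilayer.
#'
#' @param traj an unwrapped `Trajectory`.
#' @param group indices of the particles whose MSD is measured.
#' @param reference indices of the drift-reference group.
#' @param max_lag largest lag (ns); default half the trajectory length.
#' @param origin_stride origin spacing in frames (default 1 = all
#'   origins, evaluated with an FFT algorithm; larger strides use the
#'   direct sum).
#' @param lateral use x,y only (default `TRUE`).
#' @return an object of class `"MSDCurve"`: list with `lags` (ns), `msd`
#'   (Angstrom^2), `n_pairs` (origin-particle pairs averaged per lag),
#'   `group_label`.
#' @export
compute_msd <- function(traj, group, reference, max_lag = NULL,
                        origin_stride = 1L, lateral = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  if (traj$wrapped)
    abort_validation("compute_msd needs an unwrapped trajectory: call unwrap()")
  group <- as.integer(group)
  if (length(group) == 0L) abort_validation("'group' is empty")
  max_lag <- max_lag %||% ((traj$n_frames - 1L) * traj$dt / 2)
  max_m <- floor(max_lag / traj$dt + 1e-9)
  if (max_m < 1L || max_m > traj$n_frames - 1L)
    abort_validation("'max_lag' must lie in (0, (n_frames-1)*dt]")
  traj <- subtract_com_motion(traj, reference)
  dims <- if (lateral) 1:2 else 1:3
  n_g <- length(group)
  msd <- numeric(max_m + 1L)
  if (origin_stride == 1L) {
    for (i in group) {
      for (k in dims) msd <- msd + msd_fft_1d(traj$coords[, i, k], max_m)
    }
    msd <- msd / n_g
  } else {
    xmat <- do.call(cbind, lapply(dims, function(k)
      matrix(traj$coords[, group, k], nrow = traj$n_frames)))
    # direct sum averages over columns; columns hold each dim of each
    # particle, so per-particle vector norms add up correctly
    msd <- msd_direct(xmat, max_m, as.integer(origin_stride)) * length(dims)
  }
  origins_per_lag <- vapply(0:max_m, function(m)
    length(seq(1L, traj$n_frames - m, by = origin_stride)), integer(1))
  structure(
    list(lags = (0:max_m) * traj$dt, msd = msd,
         n_pairs = origins_per_lag * n_g,
         group_label = paste0(length(group), " particles")),
    class = "MSDCurve")
}

#' @export
print.MSDCurve <- function(x, ...) {
  cat(sprintf("<MSDCurve> %s, %d lags up to %g ns, MSD(max) = %.3g A^2\n",
              x$group_label, length(x$lags) - 1L, max(x$lags),
              x$msd[length(x$msd)]))
  invisible(x)
}

#' Fit the Einstein relation to an MSD curve
#'
#' Ordinary least squares of MSD against lag time inside `fit_window`;
#' the diffusion coefficient is `slope / (2 d)` converted from A^2/ns to
#' 1e-12 m^2/s (factor 1/0.01).
#'
#' @param curve an `MSDCurve`.
#' @param fit_window `c(t_min, t_max)` in ns; default the 10--50% span of
#'   the curve, skipping the short-lag ballistic/noisy regime and the
#'   poorly averaged long-lag tail.
#' @param d dimensionality of the motion (2 = lateral).
#' @return an object of class `"DiffusionEstimate"`: `d_value` and
#'   `d_uncertainty` (1e-12 m^2/s; uncertainty `NA` for a single fit),
#'   `slope` (A^2/ns), `intercept`, `r_squared`, `fit_window`, `d`.
#' @export
fit_diffusion <- function(curve, fit_window = NULL, d = 2L) {
  stopifnot(inherits(curve, "MSDCurve"))
  t_max <- max(curve$lags)
  fit_window <- fit_window %||% (c(0.1, 0.5) * t_max)
  sel <- curve$lags >= fit_window[1] & curve$lags <= fit_window[2]
  if (sum(sel) < 5L)
    abort_validation("fit window contains %d lag points; need >= 5", sum(sel))
  fit <- stats::lm(msd ~ lags, data = list(lags = curve$lags[sel],
                                           msd = curve$msd[sel]))
  slope <- unname(stats::coef(fit)[2])
  d_value <- slope / (2 * d) / D_UNIT_A2_NS
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((curve$msd[sel] - mean(curve$msd[sel]))^2)
  structure(
    list(d_value = d_value, d_uncertainty = NA_real_,
         slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
         fit_window = fit_window, d = d, n_blocks = 1L),
    class = "DiffusionEstimate")
}

#' @export
print.DiffusionEstimate <- function(x, ...) {
  unc <- if (is.na(x$d_uncertainty)) "" else sprintf(" +/- %.2g", x$d_uncertainty)
  cat(sprintf("<DiffusionEstimate> D = %.3g%s x 1e-12 m^2/s (d = %d, fit %g-%g ns)\n",
              x$d_value, unc, x$d, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Block-averaged diffusion coefficient with uncertainty
#'
#' Splits the trajectory into `n_blocks` contiguous equal spans, runs
#' [compute_msd()] and [fit_diffusion()] on each, and reports the mean
#' block estimate with an uncertainty of three times the standard error
#' of the mean across blocks (the three-sigma convention used for
#' reporting lateral diffusion coefficients).
#'
#' @inheritParams compute_msd
#' @param n_blocks number of blocks (>= 3).
#' @param fit_window fit window in ns, applied per block; default the
#'   10--50% span of `max_lag`.
#' @param d dimensionality (2 = lateral).
#' @return a `DiffusionEstimate` with `d_uncertainty` set and
#'   `block_values` attached.
#' @export
block_diffusion <- function(traj, group, reference, n_blocks = 5L,
                            max_lag = NULL, fit_window = NULL, d = 2L,
                            origin_stride = 1L, lateral = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  if (n_blocks < 3L) abort_validation("'n_blocks' must be >= 3")
  block_len <- traj$n_frames %/% n_blocks
  max_lag <- max_lag %||% ((block_len - 1L) * traj$dt / 2)
  fit_window <- fit_window %||% (c(0.1, 0.5) * max_lag)
  if (max_lag > (block_len - 1L) * traj$dt)
    abort_validation("blocks of %d frames are shorter than max_lag = %g ns",
                     block_len, max_lag)
  vals <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1L) * block_len + 1L):(b * block_len)
    sub <- trajectory(traj$coords[rows, , , drop = FALSE],
                      box = traj$box[rows, , drop = FALSE],
                      dt = traj$dt, wrapped = FALSE, masses = traj$masses)
    curve <- compute_msd(sub, group, reference, max_lag = max_lag,
                         origin_stride = origin_stride, lateral = lateral)
    vals[b] <- fit_diffusion(curve, fit_window = fit_window, d = d)$d_value
  }
  est <- structure(
    list(d_value = mean(vals),
         d_uncertainty = 3 * stats::sd(vals) / sqrt(n_blocks),
         slope = mean(vals) * 2 * d * D_UNIT_A2_NS, intercept = NA_real_,
         r_squared = NA_real_, fit_window = fit_window, d = d,
         n_blocks = n_blocks),
    class = "DiffusionEstimate")
  attr(est, "block_values") <- vals
  est
}
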