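# Internal helpers shared across modules.

# Unit conversion: 1e-12 m^2/s expressed in A^2/ns.
# 1e-12 m^2/s = 1e-12 * 1e20 A^2 / 1e9 ns = 0.01 A^2/ns.
# Applied only in gen_brownian2d (forward) and fit_diffusion (reporting).
D_UNIT_A2_NS <- 0.01

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @keywords internal
assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation("'%s' must be a single finite number", name)
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    abort_validation("'%s' must be %s %g (got %g)", name,
                     if (strict) ">" else ">=", lower, x)
  invisible(x)
}

# Minimum-image convention for displacement vectors in an orthorhombic box.
# `dx` is a matrix (n x k) of raw displacements, `box` a length-k vector.
min_image <- function(dx, box) {
  if (is.null(dim(dx))) dx <- matrix(dx, nrow = 1L)
  for (k in seq_len(ncol(dx))) {
    dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  }
  dx
}

# Wrap coordinates into [0, box) per component.
wrap_coords <- function(x, box) {
  for (k in seq_len(ncol(x))) {
    x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
  }
  x
}

# Angle between two 3-vectors, degrees in [0, 180].
vec_angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    abort_validation("zero-length vector in angle computation")
  ca <- sum(v1 * v2) / (n1 * n2)
  ca <- min(1, max(-1, ca))
  acos(ca) * 180 / pi
}

# Autocorrelation (biased, normalised by n) of a numeric vector via FFT,
# returned for lags 0..max_lag. Mean is removed first.
autocorr_fft <- function(x, max_lag) {
  n <- length(x)
  max_lag <- min(max_lag, n - 1L)
  x <- x - mean(x)
  m <- stats::nextn(2L * n, 2)
  fx <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(max_lag + 1L)] / m
  ac / n
}
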