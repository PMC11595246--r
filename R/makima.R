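# Modified Akima ("makima") piecewise-cubic interpolation.
#
# Node slopes are the weighted mean of the adjacent secant slopes with
# weights w1 = |d[i+1] - d[i]| + |d[i+1] + d[i]|/2 (and symmetrically w2),
# which keeps the interpolant and its first derivative continuous while
# damping overshoot near flat regions. Matches MATLAB's 'makima' and scipy's
# Akima1DInterpolator(method = "makima").

#' Modified Akima piecewise-cubic interpolation
#'
#' @param x Strictly increasing knot locations (length >= 2).
#' @param y Values at the knots.
#' @param xout Query locations (must lie within `[min(x), max(x)]`).
#' @return Interpolated values at `xout`.
#' @export
makima <- function(x, y, xout) {
  n <- length(x)
  if (n < 2L || length(y) != n)
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("`x` must be strictly increasing", call. = FALSE)
  if (any(xout < x[1L] - 1e-9 * abs(x[1L]) - 1e-12) ||
      any(xout > x[n] + 1e-9 * abs(x[n]) + 1e-12))
    stop("`xout` outside the knot range (no extrapolation)", call. = FALSE)
  if (n == 2L) {  # single interval: linear
    s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    return(y[1L] + s * (xout - x[1L]))
  }
  h <- diff(x)
  d <- diff(y) / h                     # secant slopes, length n-1
  # pad two phantom slopes at each end (linear extension of the secants)
  dd <- c(3 * d[1L] - 2 * d[2L], 2 * d[1L] - d[2L], d,
          2 * d[n - 1L] - d[n - 2L], 3 * d[n - 1L] - 2 * d[n - 2L])
  # dd[i + 2] == d[i]; node i uses secants i-2 .. i+1 (in d indexing)
  s <- numeric(n)
  for (i in seq_len(n)) {
    dm2 <- dd[i]; dm1 <- dd[i + 1L]; dp0 <- dd[i + 2L]; dp1 <- dd[i + 3L]
    w1 <- abs(dp1 - dp0) + abs(dp1 + dp0) / 2
    w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
    s[i] <- if (w1 + w2 == 0) 0 else (w1 * dm1 + w2 * dp0) / (w1 + w2)
  }
  # cubic Hermite evaluation
  k <- findInterval(xout, x, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  k[k >= n] <- n - 1L
  t <- (xout - x[k]) / h[k]
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[k] + h10 * h[k] * s[k] + h01 * y[k + 1L] + h11 * h[k] * s[k + 1L]
}
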