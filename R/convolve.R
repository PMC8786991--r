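# Convolution with exponential kernels and frame binning.
#
# Shared numerical kernel for the one-tissue forward model, the SRTM
# operational equation, the RPM/SRTM2 basis functions and the spectral-
# analysis bases. Curves are treated as piecewise linear on their grid and
# each segment is convolved in closed form, so the only discretisation
# error is the piecewise-linear representation itself.

#' Convolve a sampled curve with exp(-theta t)
#'
#' Computes `y(t) = integral_0^t f(s) exp(-theta (t - s)) ds` at every grid
#' point, treating `f` as piecewise linear between samples. For `theta = 0`
#' this is the running (trapezoid) integral of `f`.
#'
#' @param curve numeric vector, samples of `f` on `time_grid`.
#' @param theta kernel rate, min^-1, >= 0.
#' @param time_grid strictly increasing times in minutes (need not be
#'   uniform).
#' @return numeric vector of the convolution at `time_grid`.
#' @export
convolve_exp <- function(curve, theta, time_grid) {
  n <- length(time_grid)
  if (length(curve) != n) stop("curve and time_grid lengths differ")
  if (theta < 0) stop("theta must be >= 0")
  if (n < 2) return(rep(0, n))
  dt <- diff(time_grid)
  if (any(dt <= 0)) stop("time_grid must be strictly increasing")
  a <- curve[-n]
  b <- diff(curve) / dt
  if (theta == 0) {
    seg <- a * dt + b * dt^2 / 2
    return(c(0, cumsum(seg)))
  }
  E <- exp(-theta * dt)
  g <- (1 - E) / theta                       # int_0^dt exp(-theta(dt-u)) du
  seg <- a * g + b * (dt - g) / theta
  y <- numeric(n)
  for (i in seq_len(n - 1)) y[i + 1] <- y[i] * E[i] + seg[i]
  y
}

# Exact running integral of a piecewise-linear curve, evaluated at
# arbitrary query times inside the grid.
cum_integral_at <- function(time_grid, curve, tq) {
  n <- length(time_grid)
  cint <- c(0, cumsum((curve[-n] + curve[-1]) / 2 * diff(time_grid)))
  idx <- findInterval(tq, time_grid, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1), n - 1)
  t0 <- time_grid[idx]
  h <- tq - t0
  f0 <- curve[idx]
  slope <- (curve[idx + 1] - f0) / (time_grid[idx + 1] - t0)
  cint[idx] + f0 * h + slope * h^2 / 2
}

#' Bin a fine-grid model curve into frames
#'
#' Frame values are the time-average of the curve over each frame
#' (integral over `[start, start + duration]` divided by duration), the
#' physically correct model of frame binning. Mid-time point evaluation is
#' available as an alternative convention.
#'
#' @param time_grid,curve fine-grid model curve.
#' @param schedule a [frame_schedule()]; must lie within the grid.
#' @param sampling `"average"` (default) or `"midpoint"`.
#' @return numeric vector, one value per frame.
#' @export
frame_sample <- function(time_grid, curve, schedule,
                         sampling = c("average", "midpoint")) {
  sampling <- match.arg(sampling)
  t_end <- scan_end(schedule)
  if (t_end > time_grid[length(time_grid)] + 1e-9)
    stop(sprintf("schedule ends at %.2f min but curve grid ends at %.2f min",
                 t_end, time_grid[length(time_grid)]))
  if (sampling == "midpoint") {
    return(stats::approx(time_grid, curve, xout = frame_mid(schedule),
                         rule = 2)$y)
  }
  lo <- cum_integral_at(time_grid, curve, schedule$start)
  hi <- cum_integral_at(time_grid, curve,
                        pmin(schedule$start + schedule$duration, t_end))
  (hi - lo) / schedule$duration
}
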