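# The trajectory container: a data frame on a uniform time grid with cargo
# coordinates (um), optional attachment flags and motor position. The
# universal currency between the simulator and the statistics layer.

#' Construct a trajectory object
#'
#' @param t times (s), a strictly increasing uniform grid.
#' @param x,y cargo coordinates (um), same length as `t`.
#' @param attached optional integer/logical attachment flags.
#' @param motor_x optional motor position on the filament (um, `NA` while
#'   detached).
#' @param extra optional named list of additional columns carried through as
#'   opaque metadata.
#' @return a `data.frame` of class `trajectory` with attribute `dt`.
#' @export
trajectory <- function(t, x, y, attached = NULL, motor_x = NULL, extra = NULL) {
  if (length(t) < 2L) stop_arg("a trajectory needs at least two samples")
  if (length(x) != length(t) || length(y) != length(t)) {
    stop_arg("'x' and 'y' must have the same length as 't'")
  }
  dts <- diff(t)
  if (any(dts <= 0)) {
    stop_arg("times must be strictly increasing (first violation at row %d)",
             which(dts <= 0)[1L] + 1L)
  }
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) {
    stop_arg("time grid is not uniform (first violation at row %d)",
             which(abs(dts - dt) > 1e-6 * dt)[1L] + 1L)
  }
  df <- data.frame(t = t, x = x, y = y)
  if (!is.null(attached)) df$attached <- as.integer(attached)
  if (!is.null(motor_x)) df$motor_x <- motor_x
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  structure(df, class = c("trajectory", "data.frame"), dt = dt)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples, dt = %g s, duration = %g s\n",
              nrow(x), traj_dt(x), x$t[nrow(x)] - x$t[1L]))
  if (!is.null(x$attached)) {
    cat(sprintf("  attached fraction: %.3f\n", mean(x$attached)))
  }
  cat(sprintf("  x range [%.4g, %.4g] um, y range [%.4g, %.4g] um\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' Sampling interval of a trajectory
#' @param traj a [trajectory()].
#' @return the sampling interval in seconds.
#' @export
traj_dt <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  attr(traj, "dt")
}

#' Total duration of a trajectory
#' @param traj a [trajectory()].
#' @return duration in seconds.
#' @export
traj_duration <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$t[nrow(traj)] - traj$t[1L]
}

#' Thin a trajectory to a coarser sampling interval
#'
#' Keeps every `factor`-th sample (starting at the first), producing an
#' identical path observed on a grid `factor * dt`. Statistics evaluated at
#' lags that are multiples of the coarse interval are unchanged in
#' expectation; thinning only reduces the number of averaging windows. Used
#' to keep long-lag statistics of finely sampled trajectories affordable.
#'
#' @param traj a [trajectory()].
#' @param factor positive integer subsampling factor.
#' @return a [trajectory()] on the coarser grid.
#' @export
thin_trajectory <- function(traj, factor) {
  stopifnot(inherits(traj, "trajectory"))
  check_number(factor, "factor", lower = 1)
  factor <- as.integer(factor)
  if (factor == 1L) return(traj)
  idx <- seq(1L, nrow(traj), by = factor)
  if (length(idx) < 2L) stop_arg("thinning would leave fewer than 2 samples")
  trajectory(t = traj$t[idx], x = traj$x[idx], y = traj$y[idx],
             attached = traj$attached[idx], motor_x = traj$motor_x[idx])
}
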