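# Time-averaged trajectory statistics: TAMSD, TAMD, TAVAR, anomalous
# exponents, mean first passage times and pooled window-velocity histograms.

# Convert lag times (s) to integer sample lags, validating against the grid.
lags_to_samples <- function(traj, lags) {
  dt <- traj_dt(traj)
  n <- nrow(traj)
  if (!is.numeric(lags) || length(lags) < 1L || any(!is.finite(lags)) ||
      any(lags <= 0)) {
    stop_arg("'lags' must be positive lag times in seconds")
  }
  m <- round(lags / dt)
  if (any(abs(lags / dt - m) > 1e-6)) {
    stop_arg("each lag must be an integer multiple of the sampling interval %g s", dt)
  }
  if (any(m >= n)) stop_arg("lags must be smaller than the trajectory duration")
  if (is.unsorted(m, strictly = TRUE)) stop_arg("'lags' must be strictly increasing")
  as.integer(m)
}

new_summary_curve <- function(lags, values, statistic, extra = NULL) {
  df <- data.frame(lag = lags, value = values)
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  structure(df, class = c("summary_curve", "data.frame"), statistic = statistic)
}

#' @export
print.summary_curve <- function(x, ...) {
  cat(sprintf("summary curve <%s>: %d lags in [%g, %g] s\n",
              attr(x, "statistic"), nrow(x), min(x$lag), max(x$lag)))
  a <- attr(x, "alpha")
  if (!is.null(a)) {
    w <- attr(x, "fit_window")
    cat(sprintf("  fitted exponent alpha = %.4f over lags [%g, %g] s\n",
                a, w[1L], w[2L]))
  }
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Time-averaged mean squared displacement (TAMSD)
#'
#' Sliding-window average of the squared 2D displacement:
#' `TAMSD(Delta) = mean_i |r(t_i + Delta) - r(t_i)|^2`, with the start index
#' running over every sample.
#'
#' @param traj a [trajectory()].
#' @param lags lag times Delta (s), integer multiples of the sampling
#'   interval, strictly increasing, below the duration.
#' @return a `summary_curve` with columns `lag` (s) and `value` (um^2).
#' @export
tamsd <- function(traj, lags) {
  m <- lags_to_samples(traj, lags)
  n <- nrow(traj)
  vals <- vapply(m, function(k) {
    dx <- traj$x[(k + 1L):n] - traj$x[1L:(n - k)]
    dy <- traj$y[(k + 1L):n] - traj$y[1L:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  new_summary_curve(m * traj_dt(traj), vals, "tamsd")
}

#' Time-averaged mean displacement (TAMD)
#'
#' Sliding-window average displacement vector; a measure of directed
#' (drift) motion. Reported per component and as the vector modulus.
#'
#' @inheritParams tamsd
#' @return a `summary_curve` with columns `lag`, `value` (modulus, um),
#'   `dx` and `dy` (component means, um).
#' @export
tamd <- function(traj, lags) {
  m <- lags_to_samples(traj, lags)
  n <- nrow(traj)
  comp <- vapply(m, function(k) {
    c(mean(traj$x[(k + 1L):n] - traj$x[1L:(n - k)]),
      mean(traj$y[(k + 1L):n] - traj$y[1L:(n - k)]))
  }, numeric(2))
  new_summary_curve(m * traj_dt(traj), sqrt(comp[1L, ]^2 + comp[2L, ]^2),
                    "tamd", extra = list(dx = comp[1L, ], dy = comp[2L, ]))
}

#' Time-averaged variance (TAVAR)
#'
#' The TAMSD corrected for directed motion:
#' `TAVAR(Delta) = TAMSD(Delta) - |TAMD(Delta)|^2`. Identical to the TAMSD
#' of the drift-corrected path (window displacements with their mean removed
#' at each lag), so for purely ballistic motion it vanishes. This is the
#' discriminating statistic for run-and-rest transport: Markovian detachment
#' gives linear growth, run-length-dependent detachment with tail exponent
#' `mu` gives `Delta^(3 - mu)`.
#'
#' @inheritParams tamsd
#' @return a `summary_curve` with columns `lag` (s) and `value` (um^2).
#' @export
tavar <- function(traj, lags) {
  m <- lags_to_samples(traj, lags)
  n <- nrow(traj)
  vals <- vapply(m, function(k) {
    dx <- traj$x[(k + 1L):n] - traj$x[1L:(n - k)]
    dy <- traj$y[(k + 1L):n] - traj$y[1L:(n - k)]
    mean(dx^2 + dy^2) - mean(dx)^2 - mean(dy)^2
  }, numeric(1))
  new_summary_curve(m * traj_dt(traj), pmax(vals, 0), "tavar")
}

#' TAMSD of the drift-corrected path
#'
#' Independent route to the TAVAR: at each lag the window displacements are
#' detrended by subtracting their mean (the modification that constrains the
#' corrected path to begin and end at the same position), and the TAMSD of
#' these corrected displacements is averaged directly.
#'
#' @inheritParams tamsd
#' @return a `summary_curve` with columns `lag` (s) and `value` (um^2).
#' @seealso [tavar()]
#' @export
detrended_tamsd <- function(traj, lags) {
  m <- lags_to_samples(traj, lags)
  n <- nrow(traj)
  vals <- vapply(m, function(k) {
    dx <- traj$x[(k + 1L):n] - traj$x[1L:(n - k)]
    dy <- traj$y[(k + 1L):n] - traj$y[1L:(n - k)]
    mean((dx - mean(dx))^2 + (dy - mean(dy))^2)
  }, numeric(1))
  new_summary_curve(m * traj_dt(traj), vals, "detrended_tamsd")
}

#' Anomalous exponent from a summary curve
#'
#' Least-squares slope of `log(value)` versus `log(lag)` over an explicit
#' lag window. `alpha < 1` indicates sub-diffusion, `alpha = 1` normal
#' diffusion, `1 < alpha < 2` super-diffusion and `alpha = 2` ballistic
#' motion. The fit window is recorded on the returned value.
#'
#' @param curve a `summary_curve`.
#' @param window `c(lo, hi)` lag interval (s); at least 5 lags of the curve
#'   must fall inside it.
#' @return the fitted exponent (numeric) with attributes `window`,
#'   `intercept` (log10 prefactor) and `n_lags`.
#' @export
anomalous_exponent <- function(curve, window) {
  stopifnot(inherits(curve, "summary_curve"))
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop_arg("'window' must be c(lo, hi) with lo < hi")
  }
  sel <- curve$lag >= window[1L] & curve$lag <= window[2L]
  if (sum(sel) < 5L) stop_arg("need at least 5 lags inside the fit window")
  v <- curve$value[sel]
  if (any(v <= 0)) stop_arg("curve has nonpositive values inside the fit window")
  fit <- stats::lm(log(v) ~ log(curve$lag[sel]))
  structure(unname(coef(fit)[2L]), window = window,
            intercept = unname(coef(fit)[1L]) / log(10), n_lags = sum(sel))
}

#' Geometric lag grid
#'
#' Lags spaced geometrically between `lo` and `hi` (s), snapped to integer
#' multiples of the trajectory's sampling interval and deduplicated.
#'
#' @param traj a [trajectory()].
#' @param lo,hi lag range (s).
#' @param points_per_decade grid density (default 20).
#' @return numeric vector of lag times (s).
#' @export
lag_grid <- function(traj, lo, hi, points_per_decade = 20) {
  dt <- traj_dt(traj)
  check_number(lo, "lo", lower = dt)
  check_number(hi, "hi", lower = lo, strict_lower = TRUE)
  n_pts <- max(2L, ceiling(log10(hi / lo) * points_per_decade))
  raw <- 10^seq(log10(lo), log10(hi), length.out = n_pts)
  sort(unique(pmax(1, round(raw / dt)))) * dt
}

#' Mean first passage time along a trajectory
#'
#' For each start point on the sampling grid, the first lag at which the
#' displacement modulus `|r(t' + Delta) - r(t')|` reaches the threshold `L`
#' (first grid crossing of the level), averaged over all start points that do
#' reach `L`. Start points slide over every `stride`-th sample; starts that
#' never reach a threshold are censored and only counted.
#'
#' @param traj a [trajectory()].
#' @param distances thresholds L (um), positive, nondecreasing.
#' @param stride spacing of start points in samples (default 1: every
#'   sample).
#' @return an `mfpt_curve` data frame with columns `L` (um), `mfpt` (s; `NA`
#'   where no start reached `L`) and `n` (contributing start points).
#' @export
mfpt <- function(traj, distances, stride = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(distances) || any(distances <= 0) || is.unsorted(distances)) {
    stop_arg("'distances' must be positive and nondecreasing")
  }
  check_number(stride, "stride", lower = 1)
  res <- mfpt_kernel(traj$x, traj$y, as.numeric(distances), as.integer(stride))
  out <- data.frame(L = distances,
                    mfpt = ifelse(res$count > 0,
                                  res$total / pmax(res$count, 1L) * traj_dt(traj),
                                  NA_real_),
                    n = res$count)
  structure(out, class = c("mfpt_curve", "data.frame"))
}

#' Pooled window-velocity distribution
#'
#' Cargo speeds `|r(t' + Delta) - r(t')| / Delta` pooled over all start
#' points and over a geometric grid of lags between `delta_min` and
#' `max_fraction` of the trajectory duration (default one tenth), collected
#' into an unweighted histogram. Speed (the vector modulus) is used, giving
#' the nonnegative support under which run velocities appear as distinct
#' peaks.
#'
#' @param traj a [trajectory()].
#' @param delta_min smallest lag (s), at least the sampling interval
#'   (default: the sampling interval).
#' @param max_fraction largest lag as a fraction of the duration (default
#'   0.1).
#' @param breaks histogram bin edges (um/s), increasing; default: bins of
#'   width `bin_width` from 0 to the maximum observed speed. Supplying
#'   common breaks lets histograms from several trajectories be summed;
#'   speeds above the last edge are folded into the top bin.
#' @param bin_width bin width (um/s) used when `breaks` is `NULL`.
#' @param points_per_decade density of the geometric lag grid (default 20).
#' @return a `velocity_histogram`: data frame with columns `lower`, `upper`,
#'   `mid` (um/s) and `count`, with the lag range recorded as attributes.
#' @export
velocity_distribution <- function(traj, delta_min = traj_dt(traj),
                                  max_fraction = 0.1, breaks = NULL,
                                  bin_width = 0.05, points_per_decade = 20) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- traj_dt(traj)
  dur <- traj_duration(traj)
  check_number(delta_min, "delta_min", lower = dt)
  check_number(max_fraction, "max_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (dur < 10 * delta_min) {
    stop_arg("trajectory shorter than 10 * delta_min")
  }
  lags <- lag_grid(traj, delta_min, max_fraction * dur, points_per_decade)
  m <- as.integer(round(lags / dt))
  n <- nrow(traj)
  speeds_per_lag <- lapply(m, function(k) {
    dx <- traj$x[(k + 1L):n] - traj$x[1L:(n - k)]
    dy <- traj$y[(k + 1L):n] - traj$y[1L:(n - k)]
    sqrt(dx^2 + dy^2) / (k * dt)
  })
  if (is.null(breaks)) {
    vmax <- max(vapply(speeds_per_lag, max, numeric(1)))
    breaks <- seq(0, vmax + bin_width, by = bin_width)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop_arg("'breaks' must be strictly increasing")
  }
  counts <- integer(length(breaks) - 1L)
  top <- breaks[length(breaks)]
  for (v in speeds_per_lag) {
    h <- graphics::hist(pmin(v, top), breaks = breaks, plot = FALSE,
                        right = FALSE, include.lowest = TRUE)
    counts <- counts + h$counts
  }
  k <- length(breaks)
  structure(data.frame(lower = breaks[-k], upper = breaks[-1L],
                       mid = (breaks[-k] + breaks[-1L]) / 2, count = counts),
            class = c("velocity_histogram", "data.frame"),
            delta_range = range(lags), n_lags = length(lags))
}

#' Sum velocity histograms computed on common breaks
#'
#' @param ... `velocity_histogram` objects (or one list of them) with
#'   identical bin edges.
#' @return a pooled `velocity_histogram`.
#' @export
pool_velocity_histograms <- function(...) {
  hs <- list(...)
  if (length(hs) == 1L && !inherits(hs[[1L]], "velocity_histogram")) {
    hs <- hs[[1L]]
  }
  stopifnot(length(hs) >= 1L,
            all(vapply(hs, inherits, logical(1), "velocity_histogram")))
  base <- hs[[1L]]
  for (h in hs[-1L]) {
    if (!isTRUE(all.equal(h$lower, base$lower))) {
      stop_arg("histograms must share identical breaks to be pooled")
    }
    base$count <- base$count + h$count
  }
  base
}

#' Location of the dominant non-zero peak of a velocity histogram
#'
#' Mid-point of the most populated local maximum of the histogram at or
#' above `min_speed`. A local maximum is a bin whose (lightly smoothed)
#' count exceeds both neighbours; this separates genuine run-velocity
#' peaks from the monotonically decaying tail of the resting mass near
#' zero, which has no local maximum of its own.
#'
#' @param vh a `velocity_histogram`.
#' @param min_speed smallest speed considered (um/s, default 0.2).
#' @param smooth half-width (in bins) of the running-mean smoother applied
#'   before peak detection (default 2; 0 disables smoothing).
#' @return peak location (um/s).
#' @export
dominant_peak <- function(vh, min_speed = 0.2, smooth = 2L) {
  stopifnot(inherits(vh, "velocity_histogram"))
  cnt <- as.numeric(vh$count)
  if (smooth > 0L) {
    w <- 2L * as.integer(smooth) + 1L
    cnt <- stats::filter(cnt, rep(1 / w, w), sides = 2)
    cnt[is.na(cnt)] <- 0
  }
  n <- length(cnt)
  if (n < 3L) stop_arg("histogram too short for peak detection")
  # plateau-aware local maxima: a run of equal smoothed counts higher than
  # both flanking runs is one peak; within it the raw-count argmax locates
  # the peak bin (smoothing spreads an isolated spike into a flat plateau)
  r <- rle(as.vector(cnt))
  k <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best_mid <- NA_real_
  best_height <- -Inf
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next  # boundary runs are not peaks
    if (r$values[j] <= r$values[j - 1L] || r$values[j] <= r$values[j + 1L]) next
    idx <- starts[j]:ends[j]
    idx <- idx[vh$mid[idx] >= min_speed & vh$count[idx] > 0]
    if (length(idx) == 0L) next
    if (r$values[j] > best_height) {
      best_height <- r$values[j]
      best_mid <- vh$mid[idx[which.max(vh$count[idx])]]
    }
  }
  if (!is.finite(best_height)) {
    stop_arg("no local maximum at or above 'min_speed'")
  }
  best_mid
}
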