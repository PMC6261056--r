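# Shared helpers for the test suite.

# Log-log slope of the trajectory-averaged TAVAR over a lag window.
mean_tavar_slope <- function(trajs, window, points_per_decade = 20,
                             thin = 1L) {
  if (thin > 1L) trajs <- lapply(trajs, thin_trajectory, thin)
  lags <- lag_grid(trajs[[1L]], window[1L], window[2L], points_per_decade)
  vals <- rowMeans(vapply(trajs, function(tr) tavar(tr, lags)$value,
                          numeric(length(lags))))
  cv <- structure(data.frame(lag = lags, value = vals),
                  class = c("summary_curve", "data.frame"))
  anomalous_exponent(cv, window)
}

# Complete (interior) attached-interval durations pooled over trajectories.
attached_run_durations <- function(trajs) {
  unlist(lapply(trajs, function(tr) {
    r <- rle(tr$attached)
    keep <- r$values == 1L
    # drop runs touching either end of the recording (censored)
    if (length(r$values) >= 1L && keep[1L]) keep[1L] <- FALSE
    if (length(r$values) >= 1L && keep[length(keep)]) keep[length(keep)] <- FALSE
    r$lengths[keep] * traj_dt(tr)
  }))
}
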