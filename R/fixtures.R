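# Programmatic fixture generation: deterministic stand-ins for experimental
# recordings (1e-4 s sampling, seconds-scale durations, optional additive
# localisation noise). All fixtures are synthetic and generated in code.

#' Generate a synthetic trajectory fixture
#'
#' Deterministic (for a fixed seed) trajectories emulating the experimental
#' recordings, for tests and examples:
#' \describe{
#'   \item{ballistic}{constant velocity `v` (um/s) along x.}
#'   \item{brownian}{free Brownian cargo (fGn with H = 1/2).}
#'   \item{fgn}{free fractional-Gaussian-noise cargo with Hurst exponent
#'     `hurst`.}
#'   \item{run_rest}{one run-and-rest renewal path from a residence model
#'     (default gamma mixture, mu = 1.4, tau_d = 1 s).}
#'   \item{full_model}{the full motor-cargo simulator at reference
#'     parameters.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param params named list overriding kind-specific defaults: `duration`,
#'   `dt`, `v`, `hurst`, `amplitude`, `model`, `rest_rate`,
#'   `measurement_sigma` (nm, default 0), plus any [sim_config()] argument
#'   for `full_model`.
#' @param seed integer seed (fixtures are bit-reproducible for a fixed
#'   seed).
#' @return a [trajectory()].
#' @export
make_fixture <- function(kind = c("ballistic", "brownian", "fgn", "run_rest",
                                  "full_model"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- modifyList(list(duration = 2, dt = 1e-4, v = 1, hurst = 0.35,
                       amplitude = 0.002, drag = 0.72, rest_rate = 1,
                       measurement_sigma = 0), params)
  traj <- switch(kind,
    ballistic = {
      tt <- seq(0, p$duration, by = p$dt)
      trajectory(t = tt, x = p$v * tt, y = rep(0, length(tt)))
    },
    brownian = free_noise_fixture(0.5, p, seed),
    fgn = free_noise_fixture(p$hurst, p, seed),
    run_rest = {
      model <- if (is.null(p$model)) gamma_mixture(1.4, 1) else p$model
      ensemble_trajectories(model, n_traj = 1L, duration = p$duration,
                            v = p$v, rest_rate = p$rest_rate,
                            dt_sample = p$dt, seed = seed)[[1L]]
    },
    full_model = {
      cfg_args <- p[intersect(names(p), names(formals(sim_config)))]
      cfg_args$measurement_sigma <- NULL
      cfg_args$seed <- seed
      simulate_cargo(do.call(sim_config, cfg_args))
    })
  if (p$measurement_sigma > 0) {
    traj <- add_measurement_noise(traj, p$measurement_sigma,
                                  seed = derive_seeds(seed, 1L)[[1L]])
  }
  traj
}

free_noise_fixture <- function(hurst, p, seed) {
  n <- as.integer(round(p$duration / p$dt))
  ax <- derive_seeds(seed, 2L)
  scale <- (sqrt(p$amplitude) / p$drag) * p$dt^hurst
  xs <- cumsum(scale * generate_fgn(fgn_spec(hurst, n, p$dt, p$amplitude,
                                             seed = ax[[1L]]))$values)
  ys <- cumsum(scale * generate_fgn(fgn_spec(hurst, n, p$dt, p$amplitude,
                                             seed = ax[[2L]]))$values)
  tt <- seq(0, by = p$dt, length.out = n + 1L)
  trajectory(t = tt, x = c(0, xs), y = c(0, ys))
}
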