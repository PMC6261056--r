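# Motor-cargo simulator: forces, stepping, configuration guards, noise
# limits, run-time statistics, blocker rules, numerical convergence.

test_that("spring force is Hookean beyond the natural length and zero below", {
  # at natural length: no force
  expect_equal(spring_force(0.1, 0, 0), c(0, 0))
  expect_equal(spring_force(0.05, 0, 0), c(0, 0))
  # 8 nm of stretch along +x: magnitude 0.32 * 8 = 2.56 pN
  f <- spring_force(0.108, 0, 0)
  expect_equal(f, c(2.56, 0), tolerance = 1e-12)
  # continuity at d = l
  eps <- 1e-9
  f_above <- spring_force(0.1 + eps, 0, 0)
  expect_lt(sqrt(sum(f_above^2)), 1e-5)
  # oblique geometry: force points from cargo toward the motor
  f2 <- spring_force(0, 0, 0.2)
  expect_equal(f2[1], 0, tolerance = 1e-12)
  expect_lt(f2[2], 0)
  expect_equal(sqrt(sum(f2^2)), 0.32 * 1000 * 0.1, tolerance = 1e-9)
})

test_that("stepping rate follows the square-root stall law", {
  expect_equal(stepping_rate(0), 4 / 0.008)            # 500 / s
  expect_equal(stepping_rate(2.5), 0)                  # stall
  expect_equal(stepping_rate(2.5 / 4), 500 / 2)        # sqrt(1/4) = 1/2
  expect_equal(stepping_rate(10), 0)                   # beyond stall
})

test_that("the stability guard rejects too-coarse time steps", {
  # stepping hazard v0/d = 500/s: dt = 1e-3 gives hazard*dt = 0.5 >= 0.1
  expect_error(sim_config(duration = 1, dt = 1e-3), "hazard")
  # detachment hazard evaluated at stall load can also trip the guard
  expect_error(sim_config(duration = 1, dt = 1e-4,
                          detachment = markov_rate(1000)), "hazard")
  # the reference configuration passes
  expect_s3_class(sim_config(duration = 1, dt = 1e-4), "sim_config")
})

test_that("identical seed and config give bit-identical trajectories", {
  cfg <- sim_config(duration = 0.5, dt = 1e-4,
                    detachment = nonmarkov_rate(1.4, 1), seed = 42)
  t1 <- simulate_cargo(cfg)
  t2 <- simulate_cargo(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  expect_identical(t1$attached, t2$attached)
})

test_that("without attachment the cargo is pure fGn with TAMSD slope 2H", {
  cfg <- sim_config(duration = 20, dt = 1e-4, attach_rate = 1e-9,
                    start_attached = FALSE, hurst = 0.35, seed = 412)
  tr <- simulate_cargo(cfg)
  expect_true(all(tr$attached == 0))
  expect_true(all(is.na(tr$motor_x)))
  alphas <- vapply(1:6, function(i) {
    cfg$seed <- 900L + i
    tr <- simulate_cargo(cfg)
    curve <- tamsd(tr, lag_grid(tr, 1e-3, 1, points_per_decade = 10))
    as.numeric(anomalous_exponent(curve, c(1e-3, 1)))
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.7), 0.05)
})

test_that("deterministic transport approaches the force-balance ODE", {
  # Noise off, detachment off: the cargo is dragged by the stochastically
  # stepping motor. The mean-field oracle treats the motor as continuous
  # with velocity (1 - 2 * backstep) * kappa(F) * d and the cargo obeys
  # dx/dt = F / beta. Because kappa(F) is convex and single 8-nm steps move
  # the force by k*d = 2.56 pN (of order the stall force), the stochastic
  # system travels systematically faster than the mean-field fixed point
  # (Jensen gap ~10-15%); the oracle bounds the simulation from below.
  cfg <- sim_config(duration = 2, dt = 1e-4, noise_amplitude = 0,
                    detachment = NULL, attach_rate = 0, seed = 413)
  tr <- simulate_cargo(cfg)
  sim_dist <- tr$x[nrow(tr)]

  rhs <- function(t, state, parms) {
    stretch <- max(state[["xm"]] - state[["xc"]] - 0.1, 0)
    f <- 0.32 * 1000 * stretch
    list(c(xc = f / 0.72,
           xm = (1 - 2 * 0.25) * stepping_rate(f) * 0.008))
  }
  sol <- deSolve::ode(c(xc = 0, xm = 0), seq(0, 2, by = 1e-3), rhs, NULL)
  ode_dist <- sol[nrow(sol), "xc"]

  expect_gt(sim_dist, ode_dist)          # convexity: never slower
  expect_lt(abs(sim_dist - ode_dist) / ode_dist, 0.2)
  # averaged over seeds the gap is stable, not growing with replication
  dists <- vapply(1:10, function(i) {
    cfg$seed <- 5000L + i
    tr <- simulate_cargo(cfg)
    tr$x[nrow(tr)]
  }, numeric(1))
  expect_lt(abs(mean(dists) - ode_dist) / ode_dist, 0.2)
})

test_that("halving dt changes the mean 2-s travelled distance by < 2%", {
  mean_dist <- function(dt, n = 40L) {
    cfg <- sim_config(duration = 2, dt = dt, noise_amplitude = 0,
                      detachment = NULL, attach_rate = 0)
    mean(vapply(seq_len(n), function(i) {
      cfg$seed <- 6000L + i * (1 / dt)
      tr <- simulate_cargo(cfg)
      tr$x[nrow(tr)]
    }, numeric(1)))
  }
  d1 <- mean_dist(1e-4)
  d2 <- mean_dist(5e-5)
  expect_lt(abs(d1 - d2) / d1, 0.02)
})

test_that("force-free non-Markovian runs match the exact sampler (KS)", {
  # k -> 0 limit: the tether never transmits force, so attached intervals
  # follow the load-free residence law sampled exactly in module kinetics
  cfg <- sim_config(duration = 300, dt = 1e-4, noise_amplitude = 0,
                    stiffness = 1e-9, detachment = nonmarkov_rate(1.4, 1),
                    attach_rate = 4)
  seeds <- derive_seeds(414L, 100L)
  runs <- unlist(lapply(seeds, function(s) {
    cfg$seed <- s
    attached_run_durations(list(simulate_cargo(cfg)))
  }))
  expect_gt(length(runs), 1e4)
  ks <- suppressWarnings(
    stats::ks.test(runs, function(q) 1 - (1 / (1 + q))^1.4))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("force-free Markovian runs are exponential (KS)", {
  cfg <- sim_config(duration = 300, dt = 1e-4, noise_amplitude = 0,
                    stiffness = 1e-9, detachment = markov_rate(0.25),
                    attach_rate = 4)
  seeds <- derive_seeds(415L, 12L)
  runs <- unlist(lapply(seeds, function(s) {
    cfg$seed <- s
    attached_run_durations(list(simulate_cargo(cfg)))
  }))
  expect_gt(length(runs), 500)
  ks <- suppressWarnings(stats::ks.test(runs, stats::pexp, rate = 0.25))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("the motor never occupies or crosses the blocker cross-section", {
  cfg <- sim_config(duration = 4, dt = 1e-4,
                    detachment = nonmarkov_rate(1.4, 1), seed = 416)
  geom <- geometry(blocker = 0.3)
  half <- geom$filament_diameter / 2000
  tr <- simulate_cargo(cfg, geom)
  mx <- tr$motor_x[!is.na(tr$motor_x)]
  expect_true(all(mx <= 0.3 - half | mx >= 0.3 + half))
  # while continuously attached the motor never jumps across the blocker
  att <- !is.na(tr$motor_x)
  runs <- rle(att)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values)) {
    seg <- tr$motor_x[starts[j]:ends[j]]
    expect_true(all(seg <= 0.3 - half) || all(seg >= 0.3 + half))
  }
})

test_that("doubling D* doubles the free-cargo TAMSD exactly (same seed)", {
  mk <- function(amp) {
    simulate_cargo(sim_config(duration = 2, dt = 1e-4, attach_rate = 1e-9,
                              start_attached = FALSE, noise_amplitude = amp,
                              seed = 417))
  }
  lags <- c(0.01, 0.1, 0.5)
  t1 <- mk(0.002); t2 <- mk(0.004)
  r <- tamsd(t2, lags)$value / tamsd(t1, lags)$value
  expect_equal(r, rep(2, 3), tolerance = 1e-10)
})

test_that("measurement noise is additive, reproducible, non-destructive", {
  tr <- make_fixture("ballistic", params = list(duration = 1), seed = 1)
  noisy1 <- add_measurement_noise(tr, 20, seed = 9)
  noisy2 <- add_measurement_noise(tr, 20, seed = 9)
  expect_identical(noisy1$x, noisy2$x)
  expect_false(identical(noisy1$x, tr$x))
  # sigma is in nm; displacements are stored in um
  expect_lt(abs(sd(noisy1$x - tr$x) - 0.02), 0.002)
  expect_equal(tr$x[5], 1 * tr$t[5])  # original untouched
})

test_that("trajectory container and thinning behave", {
  expect_error(trajectory(t = c(0, 1, 1.5), x = 1:3, y = 1:3), "uniform")
  expect_error(trajectory(t = c(0, 1, 0.5), x = 1:3, y = 1:3), "increasing")
  expect_error(trajectory(t = 0, x = 0, y = 0), "two samples")
  tr <- make_fixture("brownian", params = list(duration = 1), seed = 2)
  th <- thin_trajectory(tr, 10L)
  expect_equal(traj_dt(th), 10 * traj_dt(tr), tolerance = 1e-9)
  expect_identical(th$x, tr$x[seq(1, nrow(tr), by = 10)])
  # thinned long-lag TAVAR agrees with the full-resolution value
  lags <- lag_grid(th, 0.1, 0.4, points_per_decade = 10)
  expect_equal(tavar(th, lags)$value, tavar(tr, lags)$value,
               tolerance = 0.05)
})
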