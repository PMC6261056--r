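# Coupled motor-cargo dynamics: simulation configuration, filament geometry,
# the elastic tether and stepping laws, and the per-timestep simulator.

#' Simulation configuration for the motor-cargo system
#'
#' Collects all physical and numerical parameters of one simulation. The
#' defaults are the reference dynein-droplet parameter set: tether natural
#' length 100 nm with stiffness 0.32 pN/nm, cargo drag 0.72 pN s/um,
#' 8-nm steps at unloaded speed 4 um/s, stall force 2.5 pN, detachment
#' force 3 pN, attachment rate 1/s, Hurst exponent 0.35 with noise
#' intensity 0.002 um^2/s^(2H), sampling interval 1e-4 s and a 25 percent
#' backstep probability.
#'
#' @param duration total simulated time (s), > 0.
#' @param dt time step (s); all hazards are thinned per step, and the
#'   configuration is rejected unless `max hazard * dt < 0.1`.
#' @param tether_length natural tether length l (nm).
#' @param stiffness tether stiffness k (pN/nm).
#' @param drag cargo drag coefficient beta (pN s/um).
#' @param noise_amplitude fGn intensity D* (um^2/s^(2H)); 0 switches the
#'   noise off.
#' @param hurst Hurst exponent H of the fGn, 0 < H < 1.
#' @param unloaded_speed unloaded motor speed v0 (um/s).
#' @param step_size motor step d (nm).
#' @param stall_force stall force F_s (pN): stepping rate vanishes at loads
#'   above it.
#' @param detach_force detachment force F_d (pN): Arrhenius load scale of
#'   unbinding.
#' @param detachment a detachment model ([markov_rate()], [nonmarkov_rate()]
#'   or a force-free mixture family), or `NULL` to disable detachment.
#' @param attach_rate constant attachment rate T_a (1/s), >= 0.
#' @param backstep_prob probability that a step is backward, in `[0, 1]`.
#' @param cargo_radius cargo radius R (nm); metadata only, no dynamical role.
#' @param measurement_sigma localisation error sd (nm) added by
#'   [add_measurement_noise()]; 0 (default) = off.
#' @param seed integer base seed; per-axis noise streams and the event stream
#'   are derived from it deterministically.
#' @param start_attached logical; start with the motor engaged at the origin.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration,
                       dt = 1e-4,
                       tether_length = 100,
                       stiffness = 0.32,
                       drag = 0.72,
                       noise_amplitude = 0.002,
                       hurst = 0.35,
                       unloaded_speed = 4,
                       step_size = 8,
                       stall_force = 2.5,
                       detach_force = 3,
                       detachment = nonmarkov_rate(1.4, 1, detach_force),
                       attach_rate = 1,
                       backstep_prob = 0.25,
                       cargo_radius = 250,
                       measurement_sigma = 0,
                       seed = NULL,
                       start_attached = TRUE) {
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(tether_length, "tether_length", lower = 0, strict_lower = TRUE)
  check_number(stiffness, "stiffness", lower = 0, strict_lower = TRUE)
  check_number(drag, "drag", lower = 0, strict_lower = TRUE)
  check_number(noise_amplitude, "noise_amplitude", lower = 0)
  check_number(hurst, "hurst", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(unloaded_speed, "unloaded_speed", lower = 0, strict_lower = TRUE)
  check_number(step_size, "step_size", lower = 0, strict_lower = TRUE)
  check_number(stall_force, "stall_force", lower = 0, strict_lower = TRUE)
  check_number(detach_force, "detach_force", lower = 0, strict_lower = TRUE)
  check_number(attach_rate, "attach_rate", lower = 0)
  check_number(backstep_prob, "backstep_prob", lower = 0, upper = 1)
  check_number(cargo_radius, "cargo_radius", lower = 0, strict_lower = TRUE)
  check_number(measurement_sigma, "measurement_sigma", lower = 0)
  if (!is.null(detachment) && !inherits(detachment, "detachment_model")) {
    stop_arg("'detachment' must be a detachment model or NULL")
  }
  if (!is.null(seed)) check_number(seed, "seed")
  cfg <- structure(
    list(duration = duration, dt = dt, tether_length = tether_length,
         stiffness = stiffness, drag = drag,
         noise_amplitude = noise_amplitude, hurst = hurst,
         unloaded_speed = unloaded_speed, step_size = step_size,
         stall_force = stall_force, detach_force = detach_force,
         detachment = detachment, attach_rate = attach_rate,
         backstep_prob = backstep_prob, cargo_radius = cargo_radius,
         measurement_sigma = measurement_sigma,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         start_attached = isTRUE(start_attached)),
    class = "sim_config")
  guard <- max_hazard(cfg) * dt
  if (guard >= 0.1) {
    stop_arg(paste0("unstable configuration: max hazard * dt = %.3g >= 0.1; ",
                    "reduce 'dt'"), guard)
  }
  cfg
}

# Worst-case per-step event probability used by the stability guard. The
# worst detachment load is taken at the stall force (stepping ceases above
# it, so sustained loads beyond F_s do not arise).
max_hazard <- function(cfg) {
  stepping <- cfg$unloaded_speed / (cfg$step_size / 1000)
  det <- 0
  if (!is.null(cfg$detachment)) {
    det <- detachment_rate_for_sim(cfg$detachment, 0, cfg$stall_force)
  }
  max(stepping, det, cfg$attach_rate)
}

detachment_rate_for_sim <- function(model, tau, force) {
  if (inherits(model, c("markov_rate", "nonmarkov_rate"))) {
    detachment_rate(model, tau, force)
  } else {
    effective_rate(model, tau)
  }
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: T = %g s, dt = %g s, H = %g, D* = %g\n",
              x$duration, x$dt, x$hurst, x$noise_amplitude))
  cat(sprintf("  motor: v0 = %g um/s, d = %g nm, F_s = %g pN, F_d = %g pN, backstep = %g\n",
              x$unloaded_speed, x$step_size, x$stall_force, x$detach_force,
              x$backstep_prob))
  cat(sprintf("  tether: l = %g nm, k = %g pN/nm; drag beta = %g pN s/um\n",
              x$tether_length, x$stiffness, x$drag))
  cat(sprintf("  attachment rate = %g /s; detachment: %s\n", x$attach_rate,
              if (is.null(x$detachment)) "disabled" else class(x$detachment)[1L]))
  invisible(x)
}

#' Filament geometry
#'
#' The main filament is the half-line `y = 0, x >= 0` with the plus end at
#' the origin; motion is toward +x. Optionally a perpendicular blocking
#' filament of 24-nm diameter crosses at `x = blocker` (um), and/or a
#' parallel target filament sits at `x = target` (um) for reach experiments.
#'
#' @param blocker blocker position l1 (um), or `NULL` for none.
#' @param target target-filament position l2 (um), or `NULL` for none.
#' @param filament_diameter diameter of a filament cross-section (nm).
#' @return an object of class `geometry`.
#' @export
geometry <- function(blocker = NULL, target = NULL, filament_diameter = 24) {
  if (!is.null(blocker)) check_number(blocker, "blocker", lower = 0, strict_lower = TRUE)
  if (!is.null(target)) check_number(target, "target", lower = 0, strict_lower = TRUE)
  check_number(filament_diameter, "filament_diameter", lower = 0, strict_lower = TRUE)
  structure(list(blocker = blocker, target = target,
                 filament_diameter = filament_diameter),
            class = "geometry")
}

#' Elastic tether force on the cargo
#'
#' Hookean tether between motor and cargo: zero while the motor-cargo
#' distance is below the natural length `l` (a compressed tether exerts no
#' force), otherwise of magnitude `k (d - l)` directed from the cargo toward
#' the motor. The load on the motor is the negation.
#'
#' @param motor_x motor position on the filament (um); the motor sits at
#'   `(motor_x, 0)`.
#' @param cargo_x,cargo_y cargo position (um).
#' @param tether_length natural length l (nm).
#' @param stiffness k (pN/nm).
#' @return force vector `c(fx, fy)` in pN acting on the cargo.
#' @examples
#' spring_force(0.108, 0, 0)  # 2.56 pN along +x
#' @export
spring_force <- function(motor_x, cargo_x, cargo_y,
                         tether_length = 100, stiffness = 0.32) {
  l_um <- tether_length / 1000
  k_um <- stiffness * 1000
  dx <- motor_x - cargo_x
  dy <- -cargo_y
  d <- sqrt(dx^2 + dy^2)
  if (d <= l_um || d == 0) return(c(0, 0))
  f <- k_um * (d - l_um)
  c(f * dx / d, f * dy / d)
}

#' Force-dependent stepping rate of the motor
#'
#' `kappa(F) = v0/d * (1 - sqrt(F/F_s))` for loads below the stall force,
#' zero at and above it.
#'
#' @param force load magnitude (pN), >= 0 (vectorised).
#' @param unloaded_speed v0 (um/s).
#' @param step_size d (nm).
#' @param stall_force F_s (pN).
#' @return stepping rate(s) in 1/s.
#' @examples
#' stepping_rate(0)               # 500 steps/s at v0 = 4 um/s, d = 8 nm
#' stepping_rate(2.5)             # 0: stalled
#' @export
stepping_rate <- function(force, unloaded_speed = 4, step_size = 8,
                          stall_force = 2.5) {
  validate_force(force)
  ifelse(force < stall_force,
         unloaded_speed / (step_size / 1000) * (1 - sqrt(force / stall_force)),
         0)
}

#' Simulate a motor-cargo trajectory
#'
#' Per time step of `dt`: while attached, the motor makes an 8-nm step with
#' probability `kappa(F) dt` (backward with probability `backstep_prob`),
#' never stepping into or across a blocker cross-section, and detaches with
#' probability `T_d(tau, F) dt`; while detached, it reattaches with
#' probability `T_a dt` at the filament point nearest the cargo (outside any
#' blocker). The cargo follows the explicit-Euler overdamped update
#' `dr = (F/beta) dt + noise increment`, with the fGn increments
#' pre-generated per axis from seeds derived from the base seed.
#'
#' @param config a [sim_config()].
#' @param geom a [geometry()] (default: plain filament, no blocker).
#' @return a [trajectory()] with columns `t, x, y, attached, motor_x`.
#' @export
simulate_cargo <- function(config, geom = geometry()) {
  stopifnot(inherits(config, "sim_config"), inherits(geom, "geometry"))
  n <- as.integer(round(config$duration / config$dt))
  if (n < 1L) stop_arg("'duration' must cover at least one time step")
  seeds <- derive_seeds(config$seed, 3L)
  if (config$noise_amplitude > 0) {
    scale <- (sqrt(config$noise_amplitude) / config$drag) * config$dt^config$hurst
    if (n > hosking_limit()) {
      # long sequences: one spectral draw yields both independent axes
      pair <- with_seed(seeds[[1L]],
                        davies_harte_fgn_pair(n, config$hurst))
      nx <- scale * pair[[1L]]
      ny <- scale * pair[[2L]]
    } else {
      nx <- scale * generate_fgn(fgn_spec(config$hurst, n, config$dt,
                                          config$noise_amplitude,
                                          seed = seeds[[1L]]))$values
      ny <- scale * generate_fgn(fgn_spec(config$hurst, n, config$dt,
                                          config$noise_amplitude,
                                          seed = seeds[[2L]]))$values
    }
  } else {
    nx <- numeric(n)
    ny <- numeric(n)
  }
  model <- config$detachment
  if (is.null(model)) {
    fam <- 0L; dp <- c(0, 1, 1)
  } else if (inherits(model, "markov_rate")) {
    fam <- 1L; dp <- c(model$epsilon, model$f_d, 0)
  } else if (inherits(model, "nonmarkov_rate")) {
    fam <- 2L; dp <- c(model$mu, model$tau_d, model$f_d)
  } else {
    stop_arg(paste0("the time-stepping simulator supports markov_rate, ",
                    "nonmarkov_rate or NULL detachment; mixture families ",
                    "define run-time densities (see ensemble_trajectories)"))
  }
  res <- with_seed(seeds[[3L]], simulate_kernel(
    n, config$dt,
    config$tether_length / 1000, config$stiffness * 1000, config$drag,
    config$unloaded_speed, config$step_size / 1000, config$stall_force,
    fam, dp[1L], dp[2L], dp[3L],
    config$attach_rate, config$backstep_prob,
    nx, ny,
    config$start_attached,
    !is.null(geom$blocker),
    if (is.null(geom$blocker)) 0 else geom$blocker,
    geom$filament_diameter / 2000))
  trajectory(t = seq(0, by = config$dt, length.out = n + 1L),
             x = res$x, y = res$y, attached = res$attached,
             motor_x = res$motor_x)
}

#' Simulate several independent trajectories
#'
#' Runs [simulate_cargo()] `n_traj` times with per-trajectory seeds derived
#' from `seed`, so the whole ensemble is reproducible from one base seed.
#'
#' @param config a [sim_config()] (its own `seed` field is ignored here).
#' @param n_traj number of trajectories.
#' @param geom a [geometry()].
#' @param seed base seed for the ensemble.
#' @return list of [trajectory()] objects.
#' @export
simulate_many <- function(config, n_traj, geom = geometry(), seed = NULL) {
  check_number(n_traj, "n_traj", lower = 1)
  seeds <- derive_seeds(seed, n_traj)
  lapply(seq_len(n_traj), function(i) {
    cfg <- config
    cfg$seed <- seeds[[i]]
    simulate_cargo(cfg, geom)
  })
}

#' Add Gaussian measurement noise to a trajectory
#'
#' Independent zero-mean Gaussian localisation error of standard deviation
#' `sigma` (nm) is added to each recorded coordinate, emulating tracking
#' errors; the input trajectory is not modified. On otherwise smooth
#' trajectories this produces the familiar TAVAR saturation floor of
#' `4 sigma^2` at the smallest lags (two axes times the variance of a
#' difference of two independent errors).
#'
#' @param traj a [trajectory()].
#' @param sigma localisation error sd (nm), >= 0; 0 returns the input
#'   unchanged.
#' @param seed optional integer seed.
#' @return a new [trajectory()] with noisy coordinates.
#' @export
add_measurement_noise <- function(traj, sigma, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  check_number(sigma, "sigma", lower = 0)
  if (sigma == 0) return(traj)
  s <- sigma / 1000
  n <- nrow(traj)
  noisy <- traj
  eps <- with_seed(seed, stats::rnorm(2L * n, sd = s))
  noisy$x <- traj$x + eps[seq_len(n)]
  noisy$y <- traj$y + eps[n + seq_len(n)]
  noisy
}
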