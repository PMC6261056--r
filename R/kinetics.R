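# Detachment/attachment kinetics: the Markovian (Arrhenius) and non-Markovian
# (run-length dependent) rate models, heterogeneous-motor residence-time
# densities (discrete and gamma rate mixtures, cooperative birth-death motor
# ensembles), survival functions, effective rates, samplers and power-law
# tail estimation.

#' Non-Markovian (run-length dependent) detachment model
#'
#' Hazard of unbinding that decreases with the time `tau` since the last
#' attachment: `T_d(tau, F) = mu/(tau_d + tau) * exp(F/F_d)`. Equivalent to
#' force-free run times with a power-law tail of exponent `mu` (survival
#' `(tau_d/(tau_d + tau))^mu`), the gamma-mixture limit of a heterogeneous
#' motor population.
#'
#' @param mu anomalous exponent, 1 < mu < 2.
#' @param tau_d characteristic time scale (s), > 0.
#' @param f_d detachment force (pN), > 0; scale of the Arrhenius load factor.
#' @return object of class `c("nonmarkov_rate", "detachment_model")`.
#' @export
nonmarkov_rate <- function(mu, tau_d, f_d = 3) {
  check_number(mu, "mu", lower = 1, upper = 2, strict_lower = TRUE, strict_upper = TRUE)
  check_number(tau_d, "tau_d", lower = 0, strict_lower = TRUE)
  check_number(f_d, "f_d", lower = 0, strict_lower = TRUE)
  structure(list(mu = mu, tau_d = tau_d, f_d = f_d),
            class = c("nonmarkov_rate", "detachment_model"))
}

#' Markovian detachment model
#'
#' Constant load-free unbinding rate with an Arrhenius load factor:
#' `T_d(F) = epsilon * exp(F/F_d)`, independent of the run time.
#'
#' @param epsilon load-free detachment rate (1/s), > 0.
#' @param f_d detachment force (pN), > 0.
#' @return object of class `c("markov_rate", "detachment_model")`.
#' @export
markov_rate <- function(epsilon, f_d = 3) {
  check_number(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  check_number(f_d, "f_d", lower = 0, strict_lower = TRUE)
  structure(list(epsilon = epsilon, f_d = f_d),
            class = c("markov_rate", "detachment_model"))
}

#' Discrete mixture of exponential run times
#'
#' A heterogeneous pool of motor types: type i is engaged with probability
#' `p[i]` and unbinds at constant rate `rates[i]`, so the residence-time
#' density is `sum_i p_i lambda_i exp(-lambda_i tau)`. Slow types dominate
#' long runs, making the effective detachment rate decrease with run time.
#'
#' @param p mixing probabilities (sum to 1 within 1e-12, all >= 0).
#' @param rates per-type unbinding rates (1/s), all > 0.
#' @return object of class `c("discrete_mixture", "detachment_model")`.
#' @export
discrete_mixture <- function(p, rates) {
  if (length(p) != length(rates) || length(p) < 1L) {
    stop_arg("'p' and 'rates' must be non-empty vectors of equal length")
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop_arg("'p' must be nonnegative and sum to 1 (within 1e-12)")
  }
  if (any(rates <= 0)) stop_arg("'rates' must all be > 0")
  structure(list(p = as.numeric(p), rates = as.numeric(rates)),
            class = c("discrete_mixture", "detachment_model"))
}

#' Gamma mixture of exponential run times
#'
#' Continuum limit of the heterogeneous pool: unbinding rates lambda are
#' gamma-distributed with shape `mu` and rate `tau_d`,
#' `p(lambda) = tau_d^mu lambda^(mu-1) exp(-tau_d lambda)/Gamma(mu)`.
#' Marginalising gives the power-law residence density
#' `psi(tau) = mu/(tau_d + tau) * (tau_d/(tau_d + tau))^mu` and the exactly
#' run-length dependent effective rate `mu/(tau_d + tau)`.
#'
#' @param mu shape (dimensionless), > 1.
#' @param tau_d scale time (s), > 0.
#' @return object of class `c("gamma_mixture", "detachment_model")`.
#' @export
gamma_mixture <- function(mu, tau_d) {
  check_number(mu, "mu", lower = 1, strict_lower = TRUE)
  check_number(tau_d, "tau_d", lower = 0, strict_lower = TRUE)
  structure(list(mu = mu, tau_d = tau_d),
            class = c("gamma_mixture", "detachment_model"))
}

#' Cooperative motor ensemble (birth-death) residence model
#'
#' Up to `n_max` identical motors share the cargo; with n motors bound the
#' unbinding rate is `n * unbind` and the binding rate `(n_max - n) * bind`.
#' The cargo residence time is the first passage of the bound-motor count to
#' zero, a linear combination of exponentials obtained here by
#' eigen-decomposition of the transient generator. The density has an
#' exponential tail, so this family cannot generate asymptotic
#' super-diffusion.
#'
#' @param n_max maximum number of motors, >= 1.
#' @param unbind single-motor unbinding rate (1/s), > 0.
#' @param bind per-free-motor binding rate (1/s), > 0.
#' @param initial_bound motors bound at the start of a run (default 1:
#'   the cargo has just attached), 1 <= initial_bound <= n_max.
#' @return object of class `c("cooperative_model", "detachment_model")`.
#' @export
cooperative_model <- function(n_max, unbind, bind, initial_bound = 1) {
  check_number(n_max, "n_max", lower = 1)
  if (n_max != round(n_max)) stop_arg("'n_max' must be an integer")
  check_number(unbind, "unbind", lower = 0, strict_lower = TRUE)
  check_number(bind, "bind", lower = 0, strict_lower = TRUE)
  check_number(initial_bound, "initial_bound", lower = 1, upper = n_max)
  if (initial_bound != round(initial_bound)) {
    stop_arg("'initial_bound' must be an integer")
  }
  structure(list(n_max = as.integer(n_max), unbind = unbind, bind = bind,
                 initial_bound = as.integer(initial_bound)),
            class = c("cooperative_model", "detachment_model"))
}

#' @export
print.detachment_model <- function(x, ...) {
  cat("detachment model <", class(x)[1L], ">\n", sep = "")
  str <- vapply(x, function(v) paste(format(v), collapse = ", "), character(1))
  cat(paste0("  ", names(x), " = ", str, collapse = "\n"), "\n")
  invisible(x)
}

# eigen-decomposition of the transient generator of the bound-motor chain
# (states 1..n_max; absorption at 0). Returns pieces for psi/Psi evaluation.
cooperative_decomposition <- function(model) {
  n <- model$n_max
  a <- matrix(0, n, n)
  for (j in seq_len(n)) {
    a[j, j] <- -(j * model$unbind + (n - j) * model$bind)
    if (j >= 2L) a[j - 1L, j] <- j * model$unbind
    if (j <= n - 1L) a[j + 1L, j] <- (n - j) * model$bind
  }
  e <- eigen(a)
  v <- e$vectors
  p0 <- numeric(n)
  p0[model$initial_bound] <- 1
  coefs <- solve(v, p0)
  list(values = Re(e$values), vectors = Re(v), coefs = Re(coefs))
}

# p(tau) over transient states for each tau (n_states x length(tau))
cooperative_state_probs <- function(model, tau) {
  dec <- cooperative_decomposition(model)
  expl <- exp(outer(dec$values, tau))          # n x m
  dec$vectors %*% (expl * dec$coefs)
}

validate_tau <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau < 0)) {
    stop_arg("'tau' must be nonnegative and finite")
  }
  tau
}

#' Detachment rate of a model
#'
#' Hazard of unbinding at run time `tau` under motor load `force`.
#' For the non-Markovian model this is `mu/(tau_d + tau) * exp(force/f_d)`
#' (strictly decreasing in `tau`, increasing in `force`); for the Markovian
#' model `epsilon * exp(force/f_d)` (independent of `tau`). For the mixture
#' and cooperative families (force-free constructs) it equals the effective
#' rate `psi(tau)/Psi(tau)`.
#'
#' @param model a detachment model.
#' @param tau run time(s) since the last attachment (s), >= 0.
#' @param force load force magnitude (pN), >= 0 (scalar or same length as
#'   `tau`).
#' @return rate(s) in 1/s.
#' @examples
#' detachment_rate(nonmarkov_rate(1.4, 1), tau = 0)  # 1.4 /s
#' detachment_rate(markov_rate(0.25), tau = 0)       # 0.25 /s
#' @export
detachment_rate <- function(model, tau, force = 0) {
  UseMethod("detachment_rate")
}

validate_force <- function(force) {
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0)) {
    stop_arg("'force' must be nonnegative and finite")
  }
  force
}

#' @export
detachment_rate.nonmarkov_rate <- function(model, tau, force = 0) {
  validate_tau(tau); validate_force(force)
  model$mu / (model$tau_d + tau) * exp(force / model$f_d)
}

#' @export
detachment_rate.markov_rate <- function(model, tau, force = 0) {
  validate_tau(tau); validate_force(force)
  rep_len(model$epsilon * exp(force / model$f_d), length(tau))
}

#' @export
detachment_rate.detachment_model <- function(model, tau, force = 0) {
  if (any(force != 0)) {
    stop_arg("mixture/cooperative models are force-free; 'force' must be 0")
  }
  effective_rate(model, tau)
}

#' Survival function of the run-time distribution
#'
#' Probability `Psi(tau)` that a force-free run lasts longer than `tau`.
#' For the non-Markovian rate and the gamma mixture this is the power law
#' `(tau_d/(tau_d + tau))^mu`, equal to `exp(-integral of the hazard)`.
#'
#' @inheritParams detachment_rate
#' @return survival probability/probabilities in `[0, 1]`.
#' @export
survival <- function(model, tau) UseMethod("survival")

#' @export
survival.nonmarkov_rate <- function(model, tau) {
  validate_tau(tau)
  (model$tau_d / (model$tau_d + tau))^model$mu
}

#' @export
survival.gamma_mixture <- survival.nonmarkov_rate

#' @export
survival.markov_rate <- function(model, tau) {
  validate_tau(tau)
  exp(-model$epsilon * tau)
}

#' @export
survival.discrete_mixture <- function(model, tau) {
  validate_tau(tau)
  vapply(tau, function(t) sum(model$p * exp(-model$rates * t)), numeric(1))
}

#' @export
survival.cooperative_model <- function(model, tau) {
  validate_tau(tau)
  probs <- cooperative_state_probs(model, tau)
  pmax(colSums(probs), 0)
}

#' Residence-time probability density
#'
#' Density `psi(tau)` of the force-free run time. Discrete mixture:
#' `sum_i p_i lambda_i exp(-lambda_i tau)`; gamma mixture:
#' `mu/(tau_d + tau) * (tau_d/(tau_d + tau))^mu`; cooperative model: density
#' of first passage of the bound-motor birth-death chain to zero, computed by
#' eigen-decomposition of its transient generator.
#'
#' @inheritParams detachment_rate
#' @return density value(s) in 1/s (nonnegative; integrates to 1).
#' @export
residence_pdf <- function(model, tau) UseMethod("residence_pdf")

#' @export
residence_pdf.discrete_mixture <- function(model, tau) {
  validate_tau(tau)
  vapply(tau, function(t) sum(model$p * model$rates * exp(-model$rates * t)),
         numeric(1))
}

#' @export
residence_pdf.gamma_mixture <- function(model, tau) {
  validate_tau(tau)
  model$mu / (model$tau_d + tau) * (model$tau_d / (model$tau_d + tau))^model$mu
}

#' @export
residence_pdf.nonmarkov_rate <- function(model, tau) {
  validate_tau(tau)
  model$mu / (model$tau_d + tau) * (model$tau_d / (model$tau_d + tau))^model$mu
}

#' @export
residence_pdf.markov_rate <- function(model, tau) {
  validate_tau(tau)
  model$epsilon * exp(-model$epsilon * tau)
}

#' @export
residence_pdf.cooperative_model <- function(model, tau) {
  validate_tau(tau)
  probs <- cooperative_state_probs(model, tau)
  # absorption flux: single-motor state unbinding into the empty state
  pmax(model$unbind * probs[1L, ], 0)
}

#' Effective (run-length dependent) detachment rate of a mixture
#'
#' The hazard `T_d(tau) = psi(tau)/Psi(tau)` induced by a heterogeneous or
#' cooperative motor ensemble, evaluated in log-space so that large `tau`
#' does not underflow. For a discrete mixture the value at 0 is the mean rate
#' `sum p_i lambda_i` and the long-time limit is `min(lambda_i)`; for the
#' gamma mixture it equals `mu/(tau_d + tau)` exactly.
#'
#' @inheritParams detachment_rate
#' @return effective rate(s) in 1/s.
#' @export
effective_rate <- function(model, tau) UseMethod("effective_rate")

#' @export
effective_rate.discrete_mixture <- function(model, tau) {
  validate_tau(tau)
  lp <- log(model$p)
  lr <- log(model$rates)
  vapply(tau, function(t) {
    exp(logsumexp(lp + lr - model$rates * t) - logsumexp(lp - model$rates * t))
  }, numeric(1))
}

#' @export
effective_rate.gamma_mixture <- function(model, tau) {
  validate_tau(tau)
  model$mu / (model$tau_d + tau)
}

#' @export
effective_rate.nonmarkov_rate <- function(model, tau) {
  validate_tau(tau)
  model$mu / (model$tau_d + tau)
}

#' @export
effective_rate.markov_rate <- function(model, tau) {
  validate_tau(tau)
  rep_len(model$epsilon, length(tau))
}

#' @export
effective_rate.cooperative_model <- function(model, tau) {
  validate_tau(tau)
  dec <- cooperative_decomposition(model)
  vapply(tau, function(t) {
    lt <- dec$values * t                      # log of exponential factors
    terms_psi <- model$unbind * dec$vectors[1L, ] * dec$coefs
    terms_surv <- colSums(dec$vectors) * dec$coefs
    m <- max(lt)
    num <- sum(terms_psi * exp(lt - m))
    den <- sum(terms_surv * exp(lt - m))
    num / den
  }, numeric(1))
}

#' Sample force-free run times from a detachment model
#'
#' Exact samplers: exponential for the Markovian rate; inverse transform
#' `tau = tau_d * (U^(-1/mu) - 1)` for the non-Markovian rate / gamma
#' mixture; component-then-exponential for the discrete mixture; exact
#' event-by-event simulation of the bound-motor chain for the cooperative
#' model (first passage to zero bound motors).
#'
#' @param model a detachment model.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return numeric vector of run times (s).
#' @export
sample_run_time <- function(model, n = 1, seed = NULL) {
  check_number(n, "n", lower = 1)
  with_seed(seed, sample_run_time_impl(model, as.integer(n)))
}

sample_run_time_impl <- function(model, n) UseMethod("sample_run_time_impl")

#' @export
sample_run_time_impl.markov_rate <- function(model, n) {
  stats::rexp(n, rate = model$epsilon)
}

#' @export
sample_run_time_impl.nonmarkov_rate <- function(model, n) {
  model$tau_d * (stats::runif(n)^(-1 / model$mu) - 1)
}

#' @export
sample_run_time_impl.gamma_mixture <- sample_run_time_impl.nonmarkov_rate

#' @export
sample_run_time_impl.discrete_mixture <- function(model, n) {
  comp <- sample.int(length(model$p), n, replace = TRUE, prob = model$p)
  stats::rexp(n, rate = model$rates[comp])
}

#' @export
sample_run_time_impl.cooperative_model <- function(model, n) {
  vapply(seq_len(n), function(i) {
    state <- model$initial_bound
    t <- 0
    while (state > 0L) {
      up <- (model$n_max - state) * model$bind
      down <- state * model$unbind
      t <- t + stats::rexp(1L, up + down)
      state <- if (stats::runif(1L) < down / (up + down)) state - 1L else state + 1L
    }
    t
  }, numeric(1))
}

#' Estimate the power-law tail exponent of run times
#'
#' Hill (maximum-likelihood) estimator on the upper `tail_fraction` of the
#' sample. Convention: the returned `mu` is the survival-function exponent,
#' `P(tau > t) ~ t^(-mu)`, i.e. the density tail is `t^(-mu-1)`. The
#' estimate is recomputed on half the tail as a stability check; if the two
#' disagree by more than 50 percent the tail is flagged as non-power-law
#' with a warning (e.g. exponential run times).
#'
#' @param samples run-time samples (>= 1000).
#' @param tail_fraction fraction of the largest samples used (default 0.1).
#' @return estimated tail exponent `mu_hat` with attributes `k` (tail count)
#'   and `xmin` (threshold).
#' @export
fit_tail_exponent <- function(samples, tail_fraction = 0.1) {
  if (length(samples) < 1000L) {
    stop_arg("need at least 1000 samples to estimate a tail exponent")
  }
  check_number(tail_fraction, "tail_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  x <- sort(samples[samples > 0], decreasing = TRUE)
  hill <- function(frac) {
    k <- max(10L, floor(frac * length(x)))
    xmin <- x[k + 1L]
    if (is.na(xmin) || xmin <= 0) stop_arg("too few positive tail samples")
    1 / mean(log(x[seq_len(k)] / xmin))
  }
  est <- hill(tail_fraction)
  est_half <- hill(tail_fraction / 2)
  if (abs(est_half / est - 1) > 0.5) {
    warning("tail exponent unstable across thresholds; ",
            "sample tail may not be a power law", call. = FALSE)
  }
  k <- max(10L, floor(tail_fraction * length(x)))
  structure(est, k = k, xmin = x[k + 1L])
}
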