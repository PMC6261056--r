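# Fractional Gaussian noise: exact (Hosking/Durbin-Levinson) and spectral
# (circulant-embedding) generators, plus the amplitude conventions that tie
# the noise to the cargo equation of motion.

#' Specification of a fractional Gaussian noise stream
#'
#' @param hurst Hurst exponent H, 0 < H < 1. H < 1/2 gives anti-correlated
#'   (sub-diffusive) increments, H = 1/2 white noise, H > 1/2 persistent
#'   increments.
#' @param n_steps number of increments to generate (>= 1).
#' @param dt sampling interval in seconds.
#' @param amplitude noise intensity D* in um^2/s^(2H) entering the cargo
#'   equation of motion (see [displacement_increments()]); must be >= 0.
#' @param seed integer seed, or `NULL` to use the ambient RNG state.
#' @return an object of class `fgn_spec`.
#' @seealso [generate_fgn()], [displacement_increments()]
#' @export
fgn_spec <- function(hurst, n_steps, dt, amplitude = 1, seed = NULL) {
  check_number(hurst, "hurst", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(n_steps, "n_steps", lower = 1)
  if (n_steps != round(n_steps)) stop_arg("'n_steps' must be an integer count")
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(hurst = hurst, n_steps = as.integer(n_steps), dt = dt,
         amplitude = amplitude, seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "fgn_spec"
  )
}

#' @export
print.fgn_spec <- function(x, ...) {
  cat(sprintf("fGn spec: H = %g, n = %d, dt = %g s, D* = %g um^2/s^(2H)\n",
              x$hurst, x$n_steps, x$dt, x$amplitude))
  invisible(x)
}

#' Autocovariance of unit-variance fractional Gaussian noise
#'
#' Closed form for the stationary autocovariance
#' `gamma(k) = (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)) / 2`
#' of unit-variance fGn increments at integer lag `k`. For large lags it
#' decays as `2H(2H-1) k^(2H-2)`, the slow power-law memory responsible for
#' anomalous dispersion of the integrated path.
#'
#' @param hurst Hurst exponent, 0 < H < 1.
#' @param lag nonnegative integer lag (vectorised).
#' @return autocovariance value(s); `gamma(0) = 1`.
#' @examples
#' fgn_autocovariance(0.5, 1)   # 0: Brownian increments are uncorrelated
#' fgn_autocovariance(0.35, 1)  # negative: anti-persistent
#' @export
fgn_autocovariance <- function(hurst, lag) {
  check_number(hurst, "hurst", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (!is.numeric(lag) || any(!is.finite(lag)) || any(lag < 0) ||
      any(lag != round(lag))) {
    stop_arg("'lag' must be nonnegative integer(s)")
  }
  h2 <- 2 * hurst
  0.5 * (abs(lag + 1)^h2 - 2 * abs(lag)^h2 + abs(lag - 1)^h2)
}

# Exact Durbin-Levinson (Hosking) sampler; O(n^2), for n <= hosking_limit().
hosking_fgn <- function(n, hurst) {
  acf <- fgn_autocovariance(hurst, 0:(n - 1L))
  x <- numeric(n)
  z <- stats::rnorm(n)
  v <- acf[1L]
  x[1L] <- sqrt(v) * z[1L]
  if (n == 1L) return(x)
  phi <- numeric(n - 1L)
  for (k in 1:(n - 1L)) {
    if (k == 1L) {
      phikk <- acf[2L] / v
      phi[1L] <- phikk
    } else {
      phikk <- (acf[k + 1L] - sum(phi[1:(k - 1L)] * acf[k:2L])) / v
      phi[1:(k - 1L)] <- phi[1:(k - 1L)] - phikk * phi[(k - 1L):1L]
      phi[k] <- phikk
    }
    v <- v * (1 - phikk^2)
    x[k + 1L] <- sum(phi[1:k] * x[k:1L]) + sqrt(v) * z[k + 1L]
  }
  x
}

# Largest sequence length the exact quadratic-cost method is allowed to cover.
hosking_limit <- function() 16384L

# Eigenvalues of the circulant embedding of the fGn covariance, cached for
# the most recent (length, hurst) pair: ensemble simulations request the
# same embedding thousands of times and the eigenvalue FFT is half the cost
# of a draw.
.fgn_cache <- new.env(parent = emptyenv())

dh_lambda <- function(half, hurst) {
  key <- sprintf("%d_%.17g", half, hurst)
  if (identical(.fgn_cache$key, key)) return(.fgn_cache$lambda)
  g <- fgn_autocovariance(hurst, 0:half)
  circ <- c(g, g[half:2L])
  lambda <- Re(stats::fft(circ))
  if (min(lambda) < -1e-8 * max(lambda)) {
    stop("circulant embedding produced significantly negative eigenvalues")
  }
  lambda <- pmax(lambda, 0)
  .fgn_cache$key <- key
  .fgn_cache$lambda <- lambda
  lambda
}

# Circulant-embedding (Davies-Harte) sampler for long sequences. The fGn
# covariance is positive definite and its circulant embedding has nonnegative
# eigenvalues up to round-off, which is clamped.
davies_harte_fgn <- function(n, hurst) {
  half <- max(stats::nextn(n, 2), 2L)
  m <- 2L * half
  lambda <- dh_lambda(half, hurst)
  z <- stats::rnorm(m)
  w <- complex(length.out = m)
  w[1L] <- sqrt(lambda[1L] / m) * z[1L]
  w[half + 1L] <- sqrt(lambda[half + 1L] / m) * z[2L]
  idx <- seq_len(half - 1L)
  re <- z[2L + idx]
  im <- z[2L + half - 1L + idx]
  w[1L + idx] <- sqrt(lambda[1L + idx] / (2 * m)) * complex(real = re, imaginary = im)
  w[m + 1L - idx] <- Conj(w[1L + idx])
  Re(stats::fft(w))[seq_len(n)]
}

# Two independent fGn sequences from one complex FFT: with unconstrained
# iid complex-Gaussian spectral coefficients w_k = sqrt(lambda_k/m) (a_k +
# i b_k), the real and imaginary parts of fft(w) are independent and each
# carries the circulant covariance exactly. Used by the simulator for the
# two noise axes.
davies_harte_fgn_pair <- function(n, hurst) {
  half <- max(stats::nextn(n, 2), 2L)
  m <- 2L * half
  lambda <- dh_lambda(half, hurst)
  s <- sqrt(lambda / m)
  w <- complex(real = s * stats::rnorm(m), imaginary = s * stats::rnorm(m))
  f <- stats::fft(w)
  list(Re(f)[seq_len(n)], Im(f)[seq_len(n)])
}

#' Generate a stationary fractional Gaussian noise sequence
#'
#' Produces a unit-variance, zero-mean stationary Gaussian sequence whose
#' autocovariance is [fgn_autocovariance()]. Two validated generators are
#' used: the exact recursive Durbin-Levinson (Hosking) method for sequences
#' up to 2^14 steps, and a circulant-embedding spectral method for longer
#' sequences (the exact method is quadratic in length). Output is identical
#' for identical seeds.
#'
#' @param spec an [fgn_spec()].
#' @param method `"auto"` (default: exact when it fits, spectral otherwise),
#'   `"exact"`, or `"spectral"`. Requesting `"exact"` beyond its practical
#'   length limit is an error.
#' @return an object of class `fgn`: list with `values` (unit-variance noise,
#'   length `n_steps`), `spec` and `method`.
#' @export
generate_fgn <- function(spec, method = c("auto", "exact", "spectral")) {
  stopifnot(inherits(spec, "fgn_spec"))
  method <- match.arg(method)
  n <- spec$n_steps
  if (method == "auto") {
    method <- if (n <= hosking_limit()) "exact" else "spectral"
  }
  if (method == "exact" && n > hosking_limit()) {
    stop_arg(paste0("the exact generator is limited to %d steps ",
                    "(quadratic cost); use method = \"spectral\""),
             hosking_limit())
  }
  values <- with_seed(spec$seed, {
    if (method == "exact") hosking_fgn(n, spec$hurst) else davies_harte_fgn(n, spec$hurst)
  })
  structure(list(values = values, spec = spec, method = method), class = "fgn")
}

#' @export
print.fgn <- function(x, ...) {
  cat(sprintf("fGn sequence: n = %d, H = %g, method = %s\n",
              length(x$values), x$spec$hurst, x$method))
  invisible(x)
}

#' Convert unit fGn into per-step cargo displacements
#'
#' Scales a unit-variance fGn sequence into per-step displacement increments
#' (um) of a free cargo obeying the overdamped equation of motion with drag
#' `beta` and noise intensity `amplitude` (D*). The package-wide amplitude
#' convention is: the per-axis mean squared displacement of the force-free
#' cargo is
#' \deqn{MSD(\Delta) = (D^*/\beta^2)\,\Delta^{2H} \quad [\mu m^2],}
#' i.e. each increment is `sqrt(amplitude)/beta * dt^H` times the unit noise.
#' The prefactor is a documented convention (the scaling of D* admits more
#' than one reading); statistics that matter scientifically (the anomalous
#' exponent 2H) do not depend on it.
#'
#' @param noise an `fgn` object from [generate_fgn()].
#' @param amplitude noise intensity D* (um^2/s^(2H)), >= 0.
#' @param beta drag coefficient (pN s/um), > 0.
#' @param dt time step (s), > 0; must match the sampling the noise was
#'   generated for.
#' @return numeric vector of per-step displacements in um.
#' @export
displacement_increments <- function(noise, amplitude, beta, dt) {
  stopifnot(inherits(noise, "fgn"))
  check_number(amplitude, "amplitude", lower = 0)
  check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  (sqrt(amplitude) / beta) * dt^noise$spec$hurst * noise$values
}

#' Per-step noise scale with H-independent single-step MSD
#'
#' For comparisons across Hurst exponents the single-step mean squared
#' displacement is equalised: every walker spends the same "energy" per time
#' step regardless of H. The returned per-axis, per-step displacement scale
#' is the H = 1/2 (Brownian) value `sqrt(amplitude * dt)/beta`, used for all
#' H, so that the single-step MSD is `amplitude * dt / beta^2` for every H
#' while the cumulative MSD after m steps grows as `m^(2H)`.
#'
#' @inheritParams displacement_increments
#' @param hurst Hurst exponent (validated; the returned scale is the same for
#'   every H by construction).
#' @return per-step displacement standard deviation (um) per axis.
#' @export
step_msd_calibration <- function(amplitude, hurst, dt, beta = 1) {
  check_number(hurst, "hurst", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  sqrt(amplitude * dt) / beta
}
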