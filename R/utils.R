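# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive independent sub-stream seeds from a base seed
#'
#' One base seed governs a whole run; per-trajectory and per-axis random
#' streams use seeds drawn deterministically from it, so that any component
#' can be re-run bit-identically from the base seed alone.
#'
#' @param seed integer base seed (or `NULL`, in which case `NULL`s are
#'   returned and the ambient RNG state is used downstream).
#' @param n number of sub-stream seeds to derive.
#' @return integer vector of length `n`, or a list of `NULL`s if `seed` is
#'   `NULL`.
#' @export
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(vector("list", n))
  }
  stopifnot(n >= 1)
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_arg("'%s' must be a single finite number", name)
  }
  if (strict_lower && x <= lower) stop_arg("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stop_arg("'%s' must be >= %g", name, lower)
  if (strict_upper && x >= upper) stop_arg("'%s' must be < %g", name, upper)
  if (!strict_upper && x > upper) stop_arg("'%s' must be <= %g", name, upper)
  invisible(x)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
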