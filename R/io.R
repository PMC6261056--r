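# Trajectory and configuration I/O: delimited-text trajectories (lossless to
# 12 significant digits), YAML configs with detachment-model family tags,
# result tables with metadata headers, and run manifests.

#' Write a trajectory as delimited text
#'
#' Comma-separated file with header `t,x,y[,attached,motor_x,...]`, times in
#' seconds and coordinates in um, formatted to 12 significant digits so the
#' write/read round trip is lossless at that precision.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  df <- as.data.frame(traj)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.12g", df[[nm]])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory from delimited text
#'
#' Requires columns `t`, `x`, `y`; `attached` and `motor_x` are picked up
#' when present and any further columns are preserved as opaque metadata
#' (tolerant-reader policy). The time grid must be strictly increasing and
#' uniform; violations are reported with the offending line number.
#'
#' @param path file written by [write_trajectory()] (or any conforming CSV).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop_arg("trajectory file %s is missing column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  known <- c("t", "x", "y", "attached", "motor_x")
  extra <- df[setdiff(names(df), known)]
  trajectory(t = df$t, x = df$x, y = df$y,
             attached = df$attached, motor_x = df$motor_x,
             extra = if (ncol(extra) > 0L) as.list(extra) else NULL)
}

#' Write a summary curve / result table with a metadata header
#'
#' Delimited text with `#`-prefixed metadata lines (statistic, fit window,
#' seed, anything passed in `meta`) followed by a CSV body.
#'
#' @param x a data frame (e.g. `summary_curve`, `mfpt_curve`,
#'   `velocity_histogram`, `reach_result`).
#' @param path output path.
#' @param meta named list of metadata entries for the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, meta = list()) {
  stopifnot(is.data.frame(x))
  if (!is.null(attr(x, "statistic"))) meta$statistic <- attr(x, "statistic")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(meta[[nm]]), collapse = " ")), con)
  }
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path file path.
#' @return data frame with a `meta` attribute (named character vector).
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta_lines <- sub("^#\\s*", "", lines[hdr])
  meta <- character(0)
  if (length(meta_lines) > 0L) {
    keys <- sub(":.*$", "", meta_lines)
    vals <- sub("^[^:]*:\\s*", "", meta_lines)
    meta <- stats::setNames(vals, keys)
  }
  df <- utils::read.csv(text = paste(lines[!hdr], collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

# serialise a detachment model to a tagged list and back
detachment_to_list <- function(model) {
  if (is.null(model)) return(list(family = "none"))
  fam <- class(model)[1L]
  c(list(family = fam), unclass(model))
}

detachment_from_list <- function(x) {
  fam <- x$family
  x$family <- NULL
  switch(fam,
         none = NULL,
         markov_rate = markov_rate(x$epsilon, x$f_d),
         nonmarkov_rate = nonmarkov_rate(x$mu, x$tau_d, x$f_d),
         discrete_mixture = discrete_mixture(x$p, x$rates),
         gamma_mixture = gamma_mixture(x$mu, x$tau_d),
         cooperative_model = cooperative_model(x$n_max, x$unbind, x$bind,
                                               x$initial_bound),
         stop_arg("unknown detachment family '%s'", fam))
}

#' Write a simulation configuration to a YAML file
#'
#' Flat key-value document with the detachment model stored as a tagged
#' block (`family:` plus named parameters); round-trips bit-exactly through
#' [read_sim_config()].
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$detachment <- detachment_to_list(x$detachment)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' @param path file written by [write_sim_config()] (or hand-written with
#'   the same keys). Unknown keys raise a schema error naming them.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    stop_arg("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  if (!is.null(x$detachment)) {
    # assign via [ so a "none" family yields an explicit NULL entry rather
    # than deleting the key (which would reinstate the default model)
    x["detachment"] <- list(detachment_from_list(x$detachment))
  }
  do.call(sim_config, x)
}

#' Write a run manifest
#'
#' Records everything needed to re-run a stochastic stage bit-identically:
#' the configuration snapshot, package version, base seed, derived
#' sub-stream seeds, timestamp and the list of output files.
#'
#' @param path manifest path (YAML).
#' @param config the [sim_config()] (or any serialisable list) used.
#' @param seed base seed.
#' @param outputs character vector of output file paths.
#' @param extra named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs, extra = list()) {
  cfg <- if (inherits(config, "sim_config")) {
    x <- unclass(config)
    x$detachment <- detachment_to_list(x$detachment)
    x
  } else config
  manifest <- c(list(
    package = "motorcargo",
    version = as.character(utils::packageVersion("motorcargo")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = seed,
    outputs = as.list(outputs),
    config = cfg), extra)
  yaml::write_yaml(manifest, path, precision = 17L)
  invisible(path)
}
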