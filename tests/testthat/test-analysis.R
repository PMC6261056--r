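# Trajectory statistics: TAMSD/TAMD/TAVAR identities, exponent fits,
# invariances, MFPT, velocity histograms and peak detection.

test_that("ballistic motion has the exact textbook statistics", {
  tr <- make_fixture("ballistic", params = list(duration = 2, v = 1.5))
  lags <- c(0.01, 0.05, 0.2, 0.5, 1)
  ms <- tamsd(tr, lags)
  expect_equal(ms$value, (1.5 * lags)^2, tolerance = 1e-12)
  md <- tamd(tr, lags)
  expect_equal(md$value, 1.5 * lags, tolerance = 1e-12)
  expect_equal(md$dx, 1.5 * lags, tolerance = 1e-12)
  expect_equal(md$dy, rep(0, 5))
  # directed motion carries no fluctuation: TAVAR vanishes
  tv <- tavar(tr, lags)
  expect_true(all(tv$value >= 0))
  expect_lt(max(tv$value), 1e-10)
  expect_lt(max(detrended_tamsd(tr, lags)$value), 1e-10)
})

test_that("anomalous exponent of an exact power law is exact", {
  tr <- make_fixture("ballistic", params = list(duration = 2, v = 2))
  curve <- tamsd(tr, lag_grid(tr, 0.01, 1))
  a <- anomalous_exponent(curve, c(0.01, 1))
  expect_equal(as.numeric(a), 2, tolerance = 1e-10)
  # intercept is the log10 prefactor: TAMSD = v^2 * Delta^2
  expect_equal(attr(a, "intercept"), log10(4), tolerance = 1e-8)
  expect_identical(attr(a, "window"), c(0.01, 1))
})

test_that("TAVAR equals the detrended TAMSD and never exceeds the TAMSD", {
  tr <- make_fixture("full_model", params = list(duration = 4), seed = 21)
  lags <- lag_grid(tr, 1e-3, 0.4, points_per_decade = 10)
  tv <- tavar(tr, lags)
  dtm <- detrended_tamsd(tr, lags)
  ms <- tamsd(tr, lags)
  expect_equal(tv$value, dtm$value, tolerance = 1e-10)
  expect_true(all(tv$value <= ms$value + 1e-12))
})

test_that("statistics are invariant under translation and rotation", {
  tr <- make_fixture("fgn", params = list(duration = 1), seed = 22)
  th <- 0.7
  rot <- trajectory(t = tr$t,
                    x = cos(th) * tr$x - sin(th) * tr$y + 3.2,
                    y = sin(th) * tr$x + cos(th) * tr$y - 1.1)
  lags <- c(0.001, 0.01, 0.1)
  expect_equal(tamsd(rot, lags)$value, tamsd(tr, lags)$value,
               tolerance = 1e-10)
  expect_equal(tavar(rot, lags)$value, tavar(tr, lags)$value,
               tolerance = 1e-10)
  expect_equal(tamd(rot, lags)$value, tamd(tr, lags)$value,
               tolerance = 1e-10)
})

test_that("free fGn fixture has TAMSD exponent near 2H", {
  alphas <- vapply(1:3, function(i) {
    tr <- make_fixture("fgn", params = list(duration = 10, hurst = 0.35),
                       seed = 30L + i)
    curve <- tamsd(tr, lag_grid(tr, 1e-3, 1, points_per_decade = 10))
    as.numeric(anomalous_exponent(curve, c(1e-3, 1)))
  }, numeric(1))
  expect_lt(abs(mean(alphas) - 0.7), 0.05)
})

test_that("lag validation rejects malformed lag sets", {
  tr <- make_fixture("ballistic", params = list(duration = 1))
  expect_error(tamsd(tr, numeric(0)), "lags")
  expect_error(tamsd(tr, c(-0.1, 0.1)), "lags")
  expect_error(tamsd(tr, 0.00015), "integer multiple")
  expect_error(tamsd(tr, 5), "smaller than")
  expect_error(tamsd(tr, c(0.2, 0.1)), "increasing")
})

test_that("exponent fit guards its window", {
  tr <- make_fixture("ballistic", params = list(duration = 2))
  curve <- tamsd(tr, c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5))
  expect_error(anomalous_exponent(curve, c(0.5, 0.1)), "window")
  expect_error(anomalous_exponent(curve, c(0.09, 0.11)), "at least 5")
  # TAVAR of ballistic motion is zero: nonpositive values are refused
  zcurve <- tavar(tr, c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5))
  expect_error(anomalous_exponent(zcurve, c(0.01, 0.5)), "nonpositive")
})

test_that("lag_grid returns sorted exact multiples of dt inside the range", {
  tr <- make_fixture("ballistic", params = list(duration = 2))
  g <- lag_grid(tr, 1e-3, 0.5, points_per_decade = 15)
  dt <- traj_dt(tr)
  expect_true(all(abs(g / dt - round(g / dt)) < 1e-9))
  expect_false(is.unsorted(g, strictly = TRUE))
  expect_gte(min(g), 1e-3 - 1e-12)
  expect_lte(max(g), 0.5 + 1e-12)
})

test_that("measurement noise sets a TAVAR floor of 4 sigma^2", {
  # ballistic signal + iid localisation noise of sd sigma per coordinate:
  # each lagged difference has variance 2 sigma^2 per coordinate, so the
  # 2D TAVAR plateaus at 4 sigma^2 at lags where the path itself is smooth
  tr <- make_fixture("ballistic",
                     params = list(duration = 2, measurement_sigma = 20),
                     seed = 23)
  sigma <- 0.02
  tv <- tavar(tr, c(1, 2, 5, 10, 20) * traj_dt(tr))
  expect_lt(max(abs(tv$value - 4 * sigma^2)) / (4 * sigma^2), 0.1)
})

test_that("MFPT of ballistic motion is the exact grid crossing time", {
  tr <- make_fixture("ballistic", params = list(duration = 2, v = 1))
  res <- mfpt(tr, c(0.1, 0.5, 1.0))
  expect_s3_class(res, "mfpt_curve")
  # the level is crossed after ceiling(L / (v dt)) samples; rounding of the
  # accumulated grid can delay individual starts by one sample at most
  expect_equal(res$mfpt, c(0.1, 0.5, 1.0), tolerance = 1e-3)
  # starts too close to the end are censored, not averaged
  n_total <- nrow(tr)
  expect_lt(max(abs(res$n - (n_total - c(0.1, 0.5, 1.0) / traj_dt(tr)))), 2)
  # a threshold beyond the maximum displacement yields NA with n = 0
  far <- mfpt(tr, 10)
  expect_true(is.na(far$mfpt))
  expect_identical(far$n, 0L)
  expect_error(mfpt(tr, c(0.5, 0.1)), "nondecreasing")
  # stride > 1 subsamples start points but not passage times
  res2 <- mfpt(tr, 0.5, stride = 7L)
  expect_equal(res2$mfpt, 0.5, tolerance = 1e-3)
})

test_that("velocity histogram of constant-speed motion is a single bin", {
  tr <- make_fixture("ballistic", params = list(duration = 2, v = 1))
  br <- seq(0, 2, by = 0.05)
  vh <- velocity_distribution(tr, delta_min = 0.01, breaks = br)
  expect_s3_class(vh, "velocity_histogram")
  filled <- vh$mid[vh$count > 0]
  expect_true(all(filled >= 0.95 & filled <= 1.05))
  expect_equal(dominant_peak(vh), 1.025, tolerance = 1e-9)
})

test_that("histograms pool by summing counts and reject mismatched breaks", {
  br <- seq(0, 2, by = 0.05)
  tr1 <- make_fixture("ballistic", params = list(duration = 2, v = 1))
  tr2 <- make_fixture("ballistic", params = list(duration = 2, v = 0.5))
  h1 <- velocity_distribution(tr1, delta_min = 0.01, breaks = br)
  h2 <- velocity_distribution(tr2, delta_min = 0.01, breaks = br)
  pooled <- pool_velocity_histograms(h1, h2)
  expect_identical(pooled$count, h1$count + h2$count)
  pooled2 <- pool_velocity_histograms(list(h1, h2))
  expect_identical(pooled2$count, pooled$count)
  h3 <- velocity_distribution(tr1, delta_min = 0.01, breaks = seq(0, 2, 0.1))
  expect_error(pool_velocity_histograms(h1, h3), "identical breaks")
})

test_that("dominant_peak finds a local maximum, not the resting tail", {
  mk_vh <- function(counts, width = 0.05) {
    k <- length(counts)
    br <- seq(0, by = width, length.out = k + 1L)
    structure(data.frame(lower = br[-(k + 1L)], upper = br[-1L],
                         mid = (br[-(k + 1L)] + br[-1L]) / 2,
                         count = counts),
              class = c("velocity_histogram", "data.frame"))
  }
  # decaying rest mass near zero plus a genuine bump around 1 um/s
  mid <- seq(0.025, by = 0.05, length.out = 40)
  counts <- round(4000 * exp(-mid / 0.08) + 600 * exp(-(mid - 1)^2 / 0.02))
  vh <- mk_vh(counts)
  expect_lt(abs(dominant_peak(vh) - 1), 0.06)
  # a purely decaying histogram has no admissible peak
  vh2 <- mk_vh(round(4000 * exp(-mid / 0.08)))
  expect_error(dominant_peak(vh2), "local maximum")
})
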