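write_track_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("datetime,latitude,longitude,depth", lines), f)
  f
}

test_that("track loading sorts, collapses duplicates and rejects non-UTC", {
  f <- write_track_csv(c(
    "2022-07-15T10:00:00.000Z,54.1,10.1,100",
    "2022-07-15T10:00:01.000Z,54.2,10.2,101",
    "2022-07-15T10:00:02.000Z,54.3,10.3,102"))
  tr <- load_track(f)
  expect_identical(nrow(tr), 3L)

  f2 <- write_track_csv(c(
    "2022-07-15T10:00:01.000Z,54.2,10.2,101",
    "2022-07-15T10:00:00.000Z,54.1,10.1,100"))
  tr2 <- load_track(f2)
  expect_false(is.unsorted(tr2$datetime))
  expect_true(any(grepl("reordered", tr2$flags)))

  f3 <- write_track_csv(c(
    "2022-07-15T10:00:00.000Z,54.0,10.0,100",
    "2022-07-15T10:00:00.000Z,54.2,10.2,102",
    "2022-07-15T10:00:01.000Z,54.4,10.4,104"))
  tr3 <- load_track(f3)
  expect_identical(nrow(tr3), 2L)
  expect_equal(tr3$latitude[1], 54.1)  # mean of the duplicate pair
  expect_true(grepl("duplicate", tr3$flags[1]))

  f4 <- write_track_csv("2022-07-15T10:00:00+02:00,54.1,10.1,100")
  expect_error(load_track(f4), "non-UTC.*row 1")
  f5 <- write_track_csv("not-a-time,54.1,10.1,100")
  expect_error(load_track(f5), "row 1")
})

test_that("UTC verification flags naive stamps, disorder and gaps", {
  clean <- sprintf("2022-07-15T10:00:%02d.000Z", 0:9)
  r <- verify_utc(clean)
  expect_true(r$clean)

  naive <- clean; naive[4] <- sub("Z$", "", naive[4])
  r2 <- verify_utc(naive)
  expect_false(r2$clean)
  expect_identical(r2$naive, 4L)

  # a 1 Hz track with a 60 s hole, threshold 10 s
  t <- as.POSIXct("2022-07-15 10:00:00", tz = "UTC") + c(0:9, 70:79)
  r3 <- verify_utc(paste0(format(t, "%Y-%m-%dT%H:%M:%S"), ".000Z"),
                   max_gap_seconds = 10)
  expect_identical(nrow(r3$gaps), 1L)
  expect_equal(r3$gaps$seconds, 61)

  r4 <- verify_utc(clean[c(2, 1, 3)])
  expect_true(length(r4$non_monotone) > 0)
})

test_that("injected spikes are removed exactly, clean tracks untouched", {
  # constant-position track: nothing to remove
  f <- write_track_csv(sprintf("2022-07-15T10:00:%02d.000Z,54.1,10.1,100",
                               0:29))
  tr <- load_track(f)
  out <- remove_outliers(tr, window = 11, k = 5)
  expect_identical(attr(out, "removed"), integer(0))
  expect_identical(nrow(out), 30L)

  # smooth noise-free transect with 5 known 100 m spikes
  d <- tempfile(fileext = ".csv")
  gt <- make_track(d, seed = 31, noise_sigma = 0, outliers = 5)
  tr2 <- load_track(d)
  out2 <- remove_outliers(tr2, window = 11, k = 5)
  expect_identical(attr(out2, "removed"), gt$outlier_indices)
})

test_that("wholesale deletion and short tracks are refused with warnings", {
  f <- write_track_csv(sprintf("2022-07-15T10:00:%02d.000Z,54.1,10.1,100",
                               0:4))
  tr <- load_track(f)
  expect_warning(out <- remove_outliers(tr, window = 11, k = 5),
                 "shorter than window")
  expect_identical(nrow(out), 5L)

  # pure-noise pathological track with a hair-trigger k: everything looks
  # like an outlier, so the screen must refuse rather than silently delete
  set.seed(35)
  lat <- 54.1 + rnorm(30, 0, 1e-4)
  f2 <- write_track_csv(sprintf("2022-07-15T10:00:%02d.000Z,%.8f,10.1,100",
                                0:29, lat))
  tr2 <- load_track(f2)
  expect_warning(out2 <- remove_outliers(tr2, window = 5, k = 1e-4), "50%")
  expect_identical(nrow(out2), 30L)
})

test_that("smoothing is exact on linear tracks and fixes the endpoints", {
  n <- 50
  lat <- 54 + (0:(n - 1)) * 1e-5
  lon <- 10 + (0:(n - 1)) * 2e-5
  f <- write_track_csv(sprintf("2022-07-15T10:%02d:%02d.000Z,%.8f,%.8f,100",
                               (0:(n - 1)) %/% 60, (0:(n - 1)) %% 60,
                               lat, lon))
  tr <- load_track(f)
  sm <- smooth_track(tr, window = 11)
  expect_lt(max(abs(sm$latitude - lat)), 1e-9)
  expect_lt(max(abs(sm$longitude - lon)), 1e-9)
  expect_identical(sm$latitude[1], tr$latitude[1])
  expect_identical(sm$latitude[n], tr$latitude[n])
})

test_that("smoothing shrinks white noise by about sqrt(window)", {
  set.seed(32)
  n <- 2000; window <- 11
  m_per_deg <- pi / 180 * 6371008.8
  sigma <- 2  # meters
  lat <- 54 + rnorm(n, 0, sigma) / m_per_deg
  df <- data.frame(
    datetime = as.POSIXct("2022-07-15 10:00:00", tz = "UTC") + 0:(n - 1),
    latitude = lat, longitude = 10, depth = 100, flags = "")
  tr <- structure(df, class = c("ifdo_track", "data.frame"))
  sm <- smooth_track(tr, window = window)
  core <- 6:(n - 5)  # full-window region
  resid_sd <- sd((sm$latitude[core] - 54) * m_per_deg)
  expect_gt(resid_sd, sigma / sqrt(window) * 0.8)
  expect_lt(resid_sd, sigma / sqrt(window) * 1.25)
})

test_that("interpolation is exact at knots and matches a brute-force oracle", {
  set.seed(33)
  n <- 40
  t0 <- as.POSIXct("2022-07-15 10:00:00", tz = "UTC")
  df <- data.frame(datetime = t0 + seq(0, by = 2, length.out = n),
                   latitude = cumsum(runif(n, -1e-5, 1e-5)) + 54,
                   longitude = cumsum(runif(n, -1e-5, 1e-5)) + 10,
                   depth = cumsum(runif(n, -1, 1)) + 100, flags = "")
  tr <- structure(df, class = c("ifdo_track", "data.frame"))

  at_knots <- interpolate_to(tr, tr$datetime)
  expect_equal(at_knots$latitude, tr$latitude, tolerance = 1e-12)
  expect_equal(at_knots$depth, tr$depth, tolerance = 1e-12)

  mid <- interpolate_to(tr, tr$datetime[1] + 1)
  expect_equal(mid$latitude, mean(tr$latitude[1:2]), tolerance = 1e-12)

  # brute-force per-coordinate linear interpolator as the oracle
  brute <- function(tq, tt, v) {
    j <- max(which(tt <= tq)); j <- min(j, length(tt) - 1)
    w <- (tq - tt[j]) / (tt[j + 1] - tt[j])
    v[j] + w * (v[j + 1] - v[j])
  }
  tq <- sort(runif(100, as.numeric(tr$datetime[1]),
                   as.numeric(tr$datetime[n])))
  got <- interpolate_to(tr, .POSIXct(tq, tz = "UTC"))
  tt <- as.numeric(tr$datetime)
  for (k in seq_along(tq)) {
    expect_lt(abs(got$latitude[k] - brute(tq[k], tt, tr$latitude)), 1e-12)
    expect_lt(abs(got$longitude[k] - brute(tq[k], tt, tr$longitude)), 1e-12)
  }
})

test_that("extrapolation is tolerated near the span and refused beyond", {
  t0 <- as.POSIXct("2022-07-15 10:00:00", tz = "UTC")
  df <- data.frame(datetime = t0 + 0:9, latitude = 54, longitude = 10,
                   depth = 100, flags = "")
  tr <- structure(df, class = c("ifdo_track", "data.frame"))
  r <- interpolate_to(tr, c(t0 - 3, t0 - 10, t0 + 12, t0 + 20))
  expect_identical(r$ok, c(TRUE, FALSE, TRUE, FALSE))
  expect_match(r$message[2], "outside track span")
})

test_that("uncertainty grows with the bracketing displacement", {
  t0 <- as.POSIXct("2022-07-15 10:00:00", tz = "UTC")
  m_per_deg <- pi / 180 * 6371008.8
  df <- data.frame(datetime = t0 + 0:2,
                   latitude = 54 + c(0, 10 / m_per_deg, 10 / m_per_deg),
                   longitude = 10, depth = 100, flags = "")
  tr <- structure(df, class = c("ifdo_track", "data.frame"))
  r <- interpolate_to(tr, c(t0 + 0.5, t0 + 1.5),
                      sensor_uncertainty_meters = 2)
  expect_equal(r$uncertainty_meters[1], 2 + 5, tolerance = 1e-6)
  expect_equal(r$uncertainty_meters[2], 2 + 0, tolerance = 1e-6)
})

test_that("curation recovers the true trajectory from noise and spikes", {
  d <- tempfile(fileext = ".csv")
  gt <- make_track(d, seed = 34, noise_sigma = 1, outliers = 5,
                   spike_magnitude = 100)
  tr <- load_track(d)
  m_per_deg <- pi / 180 * 6371008.8
  err_m <- function(track) {
    truth <- gt$truth
    idx <- match(as.numeric(track$datetime), as.numeric(truth$datetime))
    dx <- (track$longitude - truth$longitude[idx]) * m_per_deg *
      cos(54.33 * pi / 180)
    dy <- (track$latitude - truth$latitude[idx]) * m_per_deg
    sqrt(mean(dx^2 + dy^2))
  }
  raw_rms <- err_m(tr)
  cur <- smooth_track(remove_outliers(tr, 11, 5), 11)
  cur_rms <- err_m(cur)
  expect_lt(cur_rms, raw_rms)
  expect_lt(cur_rms, gt$spike_magnitude / 3)
  # curation preserves strict time ordering and invents no samples
  expect_false(is.unsorted(cur$datetime, strictly = TRUE))
  expect_lte(nrow(cur), nrow(tr))
})
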