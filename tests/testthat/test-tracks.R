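test_that("make_track builds a sorted track from published fisher fixes", {
  path <- system.file("extdata", "fisher_f2_first10.csv", package = "homerange")
  raw <- read.csv(path, check.names = FALSE)
  trk <- make_track(raw, x, y, t, crs = 5070, id = id, hdop = hdop)
  expect_s3_class(trk, "hr_track")
  expect_equal(nrow(trk), 10L)
  expect_equal(trk$t[1], as.POSIXct("2011-01-01 00:00:30", tz = "UTC"))
  expect_equal(trk$hdop[1], 10.5)
  expect_equal(get_crs(trk), 5070L)
  expect_false(attr(trk, "geographic"))
})

test_that("make_track handles minimal, unsorted and malformed inputs", {
  t0 <- as.POSIXct("2011-01-01", tz = "UTC")
  one <- make_track(data.frame(a = 0, b = 0, tm = t0), a, b, tm, crs = 5070)
  expect_equal(nrow(one), 1L)

  rev_in <- data.frame(x = 3:1, y = c(30, 20, 10), t = t0 + c(300, 200, 100))
  trk <- make_track(rev_in, x, y, t, crs = 5070)
  expect_equal(trk$x, 1:3)
  expect_equal(trk$y, c(10, 20, 30))
  expect_true(all(diff(as.numeric(trk$t)) > 0))
  # sorting is idempotent
  trk2 <- make_track(as.data.frame(trk), x, y, t, crs = 5070)
  expect_equal(trk2$x, trk$x)

  expect_error(make_track(data.frame(x = 1, y = 1, t = t0), x, y, missing_col,
                          crs = 5070), class = "hr_error_schema")
  expect_error(make_track(data.frame(x = 1, y = 1, t = "not a time"),
                          x, y, t, crs = 5070), class = "hr_error_schema")
  expect_error(make_track(data.frame(x = Inf, y = 1, t = t0), x, y, t, crs = 5070),
               class = "hr_error_schema")
})

test_that("duplicate timestamps are dropped keeping the first fix", {
  t0 <- as.POSIXct("2011-01-01", tz = "UTC")
  d <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3), t = t0 + c(0, 0, 60))
  expect_warning(trk <- make_track(d, x, y, t, crs = 5070), "duplicate")
  expect_equal(nrow(trk), 2L)
  expect_equal(trk$x[1], 1)
})

test_that("geographic tracks are flagged and refused by estimators", {
  t0 <- as.POSIXct("2011-01-01", tz = "UTC")
  trk <- make_track(data.frame(x = runif(10), y = runif(10), t = t0 + 1:10),
                    x, y, t, crs = 4326)
  expect_true(attr(trk, "geographic"))
  expect_error(hr_mcp(trk), class = "hr_error_domain")
})

test_that("resample_track keeps the first in-tolerance fix per window", {
  t0 <- as.POSIXct("2011-01-01", tz = "UTC")
  # fixes every 10 min for 3 h
  trk <- toy_track(seq_len(19), seq_len(19), dt = 1)
  trk$t <- t0 + seq(0, 180, by = 10) * 60
  trk <- make_track(as.data.frame(trk), x, y, t, crs = 5070)
  out <- resample_track(trk, interval = 3600, tolerance = 300)
  expect_equal(nrow(out), 4L)
  expect_equal(as.numeric(out$t - t0, units = "hours"), 0:3)

  # already-hourly track is unchanged (idempotence)
  hourly <- resample_track(out, interval = 3600, tolerance = 300)
  expect_equal(as.data.frame(hourly), as.data.frame(out))

  # fixes at 0 and 59 min only: the 59-min fix misses its window anchor
  two <- make_track(data.frame(x = c(0, 1), y = c(0, 1), t = t0 + c(0, 59 * 60)),
                    x, y, t, crs = 5070)
  expect_equal(nrow(resample_track(two, 3600, 300)), 1L)

  # never interpolates: every output fix exists in the input
  irr <- make_track(data.frame(x = rnorm(40), y = rnorm(40),
                               t = t0 + sort(sample(0:7200, 40))),
                    x, y, t, crs = 5070)
  res <- resample_track(irr, 600, 60)
  expect_lte(nrow(res), nrow(irr))
  expect_true(all(res$x %in% irr$x))

  empty <- make_track(data.frame(x = numeric(0), y = numeric(0),
                                 t = as.POSIXct(character(0), tz = "UTC")),
                      x, y, t, crs = 5070)
  expect_equal(nrow(resample_track(empty, 3600, 60)), 0L)
  expect_error(resample_track(irr, -1, 0), class = "hr_error_domain")
})

test_that("floor_week floors to the configured week start", {
  t1 <- as.POSIXct("2011-01-05 13:00:00", tz = "UTC")  # a Wednesday
  expect_equal(floor_week(t1), as.POSIXct("2011-01-03", tz = "UTC"))
  # a boundary instant maps to itself (idempotence)
  b <- as.POSIXct("2011-01-03 00:00:00", tz = "UTC")
  expect_equal(floor_week(b), b)
  expect_equal(floor_week(floor_week(t1)), floor_week(t1))
  # two instants in the same week agree
  expect_equal(floor_week(t1), floor_week(t1 + 86400))
  # Sunday start shifts the boundary
  expect_equal(floor_week(t1, week_start = 7), as.POSIXct("2011-01-02", tz = "UTC"))
})

test_that("group_tracks partitions rows and honours min_n", {
  t0 <- as.POSIXct("2011-01-01", tz = "UTC")
  d <- data.frame(
    x = rnorm(30), y = rnorm(30),
    t = rep(t0 + 1:10, 3) + rep(c(0, 1e6, 2e6), each = 10),
    id = rep(c("a", "b", "c"), each = 10)
  )
  d <- d[sample(nrow(d)), ]
  trk <- make_track(d, x, y, t, crs = 5070, id = id)
  g <- group_tracks(trk, by = "id")
  expect_equal(nrow(g), 3L)
  expect_equal(sort(g$n), c(10L, 10L, 10L))
  # concatenating groups is a permutation of the input rows
  back <- do.call(rbind, lapply(g$track, function(tr) as.data.frame(tr)[c("x", "y")]))
  expect_setequal(round(back$x, 10), round(d$x, 10))
  # single-group input round-trips
  g1 <- group_tracks(trk, by = "id", min_n = 11L)
  expect_equal(nrow(g1), 0L)
  expect_error(group_tracks(trk, by = "nope"), class = "hr_error_schema")
})

test_that("CSV dialects round-trip and movebank requires a projection", {
  t0 <- as.POSIXct("2011-01-01", tz = "UTC")
  trk <- simulate_track("ou", n = 100, dt = 3600, mu = c(1.78e6, 2.40e6),
                        sigma2 = 1e6, tau_pos = 6 * 3600, uere = 1.5,
                        hdop_law = "lognormal", seed = 21)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracks(trk, p, dialect = "generic_csv")
  back <- read_tracks(p, dialect = "generic_csv", crs = 5070)
  expect_equal(back$x, trk$x, tolerance = 1e-12)
  expect_equal(max(abs(back$x - trk$x)), 0, tolerance = 1e-9)
  expect_equal(back$hdop, trk$hdop, tolerance = 1e-12)
  expect_equal(as.numeric(back$t), as.numeric(trk$t))

  pm <- withr::local_tempfile(fileext = ".csv")
  write_tracks(trk, pm, dialect = "movebank_csv")
  expect_error(read_tracks(pm, dialect = "movebank_csv"), class = "hr_error_domain")
  mb <- read_tracks(pm, dialect = "movebank_csv", crs = 5070)
  # projection round-trip: forward(inverse(x)) recovers coordinates
  expect_lt(max(abs(mb$x - trk$x)), 1e-6)
  expect_lt(max(abs(mb$y - trk$y)), 1e-6)
  expect_error(read_tracks(p, dialect = "generic_csv"), class = "hr_error_domain")
  expect_error(read_tracks("no-such-file.csv", dialect = "generic_csv", crs = 5070),
               class = "hr_error_schema")
})

test_that("projected distances agree with great-circle distances", {
  skip_if_not_installed("geosphere")
  # pairs of nearby points in the CONUS Albers domain of use
  lon <- c(-75.2, -75.18, -93.1, -93.05)
  lat <- c(43.5, 43.52, 36.2, 36.24)
  pr <- project_lonlat(lon, lat, 5070)
  d_proj <- sqrt(diff(pr$x)[c(1, 3)]^2 + diff(pr$y)[c(1, 3)]^2)
  d_geo <- c(
    geosphere::distGeo(c(lon[1], lat[1]), c(lon[2], lat[2])),
    geosphere::distGeo(c(lon[3], lat[3]), c(lon[4], lat[4]))
  )
  expect_lt(max(abs(d_proj / d_geo - 1)), 0.005)

  # UTM zone 18N around its central meridian
  pr2 <- project_lonlat(c(-75.1, -75.05), c(43.0, 43.03), 32618)
  d2 <- sqrt(diff(pr2$x)^2 + diff(pr2$y)^2)
  dg2 <- geosphere::distGeo(c(-75.1, 43.0), c(-75.05, 43.03))
  expect_lt(abs(d2 / dg2 - 1), 0.005)

  expect_error(project_lonlat(0, 0, 123456), class = "hr_error_unsupported")
})

test_that("GeoJSON point export is valid and complete", {
  trk <- simulate_track("iid", n = 5, sigma2 = 1e4, uere = 1, seed = 3)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_track_geojson(trk, p)
  gj <- jsonlite::read_json(p)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 5L)
  expect_equal(gj$features[[1]]$geometry$type, "Point")
  expect_true(!is.null(gj$features[[1]]$properties$hdop))
})
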