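test_that("track interpolation is linear and preserves endpoints", {
  t0 <- as.POSIXct("2017-03-01 00:00:00", tz = "UTC")
  tr <- Track(c(t0, t0 + 7200), c(37, 38), c(-122, -121))
  out <- trackData(interpolateTrack(tr, 1))
  expect_equal(nrow(out), 3)
  expect_equal(out$lat[2], 37.5)
  expect_equal(out$lon[2], -121.5)
  expect_equal(out$lat[c(1, 3)], c(37, 38))

  hourly <- Track(t0 + 3600 * 0:5, 37 + 0:5 / 10, -122 + 0:5 / 10)
  expect_equal(trackData(interpolateTrack(hourly, 1)), trackData(hourly))

  # convexity: outputs stay inside the input bounding box
  set.seed(1)
  tr2 <- Track(t0 + sort(runif(8, 0, 1e5)), runif(8, 30, 40), runif(8, -130, -120))
  out2 <- trackData(interpolateTrack(tr2, 1))
  expect_true(all(out2$lat >= 30 & out2$lat <= 40))
  expect_true(all(out2$lon >= -130 & out2$lon <= -120))

  expect_error(interpolateTrack(Track(c(t0, t0), c(1, 2), c(1, 2))),
               "duplicate")
})

test_that("haversine distances match closed forms and the law-of-cosines oracle", {
  expect_equal(greatCircleKm(10, 20, 10, 20), 0)
  expect_equal(greatCircleKm(0, 0, 0, 1), 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_equal(greatCircleKm(0, 0, 90, 0), pi * 6371 / 2, tolerance = 1e-6)
  # symmetry
  expect_equal(greatCircleKm(12, 34, -45, 120), greatCircleKm(-45, 120, 12, 34))

  set.seed(2)
  la1 <- runif(200, -80, 80); lo1 <- runif(200, -179, 179)
  la2 <- runif(200, -80, 80); lo2 <- runif(200, -179, 179)
  hv <- greatCircleKm(la1, lo1, la2, lo2)
  lc <- lawOfCosinesKm(la1, lo1, la2, lo2)
  far <- hv > 1
  expect_lt(max(abs(hv[far] - lc[far]) / hv[far]), 1e-6)
})

test_that("trip distances follow the track geometry", {
  t0 <- 1.5e9
  still <- Track(t0 + 3600 * 0:5, rep(37, 6), rep(-122, 6))
  d <- tripDistances(still, c(36, -122))
  expect_equal(d$total_km, 0)
  expect_equal(d$max_from_colony_km, greatCircleKm(37, -122, 36, -122))

  # out-and-back along a meridian
  lat <- c(seq(37, 39, length.out = 11), seq(38.8, 37, length.out = 10))
  ob <- Track(t0 + 3600 * seq_along(lat), lat, rep(-122, length(lat)))
  d2 <- tripDistances(ob, c(37, -122))
  L <- greatCircleKm(37, -122, 39, -122)
  expect_equal(d2$total_km, 2 * L, tolerance = 1e-6)
  expect_equal(d2$max_from_colony_km, L, tolerance = 1e-6)

  rw <- healthyTrip()@track
  d3 <- tripDistances(rw, c(37.108, -122.336))
  expect_gte(d3$total_km, d3$max_from_colony_km)
})

test_that("solar elevation matches the almanac ephemeris within 0.5 degrees", {
  expect_equal(solarElevation(as.POSIXct("2017-03-20 12:07:00", tz = "UTC"),
                              0, 0), 90, tolerance = 0.02)
  expect_lt(solarElevation(as.POSIXct("2017-12-21 12:00:00", tz = "UTC"),
                           80, 0), 0)
  set.seed(3)
  tt <- as.POSIXct("2015-01-01", tz = "UTC") + runif(500, 0, 6 * 365 * 86400)
  la <- runif(500, -70, 70); lo <- runif(500, -180, 180)
  expect_lt(max(abs(solarElevation(tt, la, lo) - almanacElevation(tt, la, lo))),
            0.5)
  # smoothness: elevation changes by well under 0.5 degrees per minute
  expect_lt(max(abs(solarElevation(tt + 60, la, lo) -
                      solarElevation(tt, la, lo))), 0.5)
  expect_error(solarElevation(as.POSIXct("1900-01-01", tz = "UTC"), 0, 0),
               "1950")
})

test_that("day/night classification interpolates locations and flags dives", {
  trip <- healthyTrip()
  dv <- classifyDayNight(trip@truthDives, trip@track)
  d <- diveData(dv)
  expect_true(all(!is.na(d$is_day)))
  expect_true(all(!is.na(d$lat)))
  # flags agree with the elevation sign at the dive position
  elev <- solarElevation(d$start_time, d$lat, d$lon)
  expect_identical(d$is_day, elev > 0)

  # noon at the equator is day; local midnight at mid-latitude is night
  t0 <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC")
  tr <- Track(c(t0, t0 + 86400), c(0, 0), c(0, 0))
  mk <- function(ts) DiveTable(data.frame(
    start_idx = 1L, end_idx = 10L, start_time = as.numeric(ts),
    end_time = as.numeric(ts) + 600, max_depth = 100, duration_min = 10,
    bottom_time_min = 5, n_wiggles = 0L, descent_rate = 1, ascent_rate = 1,
    pdi_min = NA_real_, is_day = NA, lat = NA_real_, lon = NA_real_))
  expect_true(diveData(classifyDayNight(mk(t0 + 12 * 3600), tr))$is_day)
  expect_false(diveData(classifyDayNight(mk(t0 + 3600), tr))$is_day)

  # dives outside the track span are left unlocated
  far <- classifyDayNight(mk(t0 + 3 * 86400), tr)
  expect_true(is.na(diveData(far)$is_day))
  expect_true(is.na(diveData(far)$lat))
})

test_that("an equatorial trip splits dives roughly half day, half night", {
  cfg <- simConfig(seed = 41, tripDays = 10, colonyLatLon = c(0, -140),
                   dailyDisplacement = 20)
  trip <- simulateTrip(cfg)
  d <- diveData(classifyDayNight(trip@truthDives, trip@track))
  expect_equal(mean(d$is_day, na.rm = TRUE), 0.5, tolerance = 0.04)
})
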