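processedTrip <- function(trip) {
  dives <- classifyDayNight(trip@truthDives, trip@track)
  list(dives = dives, trip = trip)
}

test_that("trip summary reproduces generator truth on a healthy trip", {
  p <- processedTrip(healthyTrip())
  cfg <- p$trip@config
  ts <- tripSummary(p$dives, p$trip@track, p$trip@morphometryPair,
                    events = p$trip@jawEvents,
                    colony = cfg@colonyLatLon)
  m <- ts@metrics
  expect_equal(m$trip_duration_days, cfg@tripDays, tolerance = 0.01)
  expect_equal(m$n_dives, nDives(p$dives))

  d <- diveData(p$dives)
  nP <- sum(!is.na(d$pdi_min))
  expect_lt(abs(m$pdi_min$all["mean"] - cfg@pdiMean),
            3 * cfg@pdiSd / sqrt(nP))
  expect_lt(abs(m$duration_min$all["mean"] - cfg@diveDurationMean),
            3 * cfg@diveDurationSd / sqrt(nrow(d)))
  # diel depth structure survives into the summary
  expect_gt(m$max_depth_m$day["mean"], m$max_depth_m$night["mean"])
  expect_equal(m$n_day_dives + m$n_night_dives, m$n_located_dives)
  # energy/mass direction: 294 -> 245 kg synthetic pair loses mass & energy
  expect_lt(m$mass_gain_kg, 0)
  expect_lt(m$energy_gain_MJ, 0)
  expect_gte(m$total_distance_km, m$max_distance_km)
})

test_that("identical morphometry with no fasting gives zero mass gain", {
  p <- processedTrip(healthyTrip())
  same <- syntheticMorphometry(294, 0.247, "departure", fastingDays = 0)
  sameArr <- syntheticMorphometry(294, 0.247, "arrival", fastingDays = 0)
  ts <- tripSummary(p$dives, p$trip@track,
                    list(departure = same, arrival = sameArr))
  expect_equal(ts@metrics$mass_gain_kg, 0)
  expect_equal(ts@metrics$energy_gain_MJ, 0, tolerance = 1e-9)
  expect_error(tripSummary(p$dives, p$trip@track, list(departure = same)),
               "arrival")
})

test_that("sick trips show more extended PDIs than healthy at fixed seeds", {
  pH <- processedTrip(healthyTrip())
  pS <- processedTrip(sickTrip())
  nH <- extendedSurfaceIntervals(pH$dives, 4)$count
  nS <- extendedSurfaceIntervals(pS$dives, 4)$count
  expect_gt(nS, nH)
})

test_that("2-D kernel density integrates to 1 and matches the direct sum", {
  set.seed(8)
  x <- rnorm(400, 500, 120)
  y <- rnorm(400, 20, 5)
  k <- diveKDE2d(x, y)
  dx <- diff(k$x[1:2]); dy <- diff(k$y[1:2])
  expect_equal(sum(k$z) * dx * dy, 1, tolerance = 0.01)

  nodes <- cbind(sample(64, 20, replace = TRUE), sample(64, 20, replace = TRUE))
  direct <- kdeDirect(k$x[nodes[, 1]], k$y[nodes[, 2]], x, y,
                      k$bandwidth[1], k$bandwidth[2])
  expect_equal(k$z[nodes], direct, tolerance = 1e-9)

  # a single tight cluster puts the mode at the cluster centre
  xc <- rnorm(200, 100, 0.5); yc <- rnorm(200, 50, 0.5)
  kc <- diveKDE2d(xc, yc)
  mode <- which(kc$z == max(kc$z), arr.ind = TRUE)
  expect_equal(kc$x[mode[1]], 100, tolerance = 0.05)
  expect_equal(kc$y[mode[2]], 50, tolerance = 0.05)

  # axis rescaling with matched bandwidth scaling moves the mode with it
  ks <- diveKDE2d(x * 10, y, bandwidth = c(k$bandwidth[1] * 10, k$bandwidth[2]))
  modeA <- which(k$z == max(k$z), arr.ind = TRUE)
  modeB <- which(ks$z == max(ks$z), arr.ind = TRUE)
  expect_equal(ks$x[modeB[1]] / 10, k$x[modeA[1]], tolerance = 0.02)

  expect_error(diveKDE2d(rep(1, 50), y[1:50]), "degenerate")
  expect_error(diveKDE2d(1:5, 1:5), "at least 10")
})

test_that("cumulative PDI curves are proper CDFs and separate sick from healthy", {
  flat <- cumulativePdiCurve(rep(2, 10))
  expect_true(all(flat$pdi_min == 2))
  expect_equal(max(flat$cdf), 1)

  pS <- diveData(sickTrip()@truthDives)$pdi_min
  pH <- diveData(healthyTrip()@truthDives)$pdi_min
  cS <- cumulativePdiCurve(pS)
  expect_true(all(diff(cS$cdf) >= 0))
  expect_equal(cS$cdf[nrow(cS)], 1)

  # beyond the 98th percentile the sick curve sits at longer PDIs
  q98S <- min(cumulativePdiCurve(pS, topQuantile = 0.98)$pdi_min)
  q98H <- min(cumulativePdiCurve(pH, topQuantile = 0.98)$pdi_min)
  expect_gt(q98S, q98H)

  # day/night split covers all non-NA PDIs
  d <- diveData(classifyDayNight(sickTrip()@truthDives, sickTrip()@track))
  cv <- cumulativePdiCurve(d$pdi_min, d$is_day)
  expect_setequal(unique(cv$split), c("day", "night"))
  expect_equal(nrow(cv), sum(!is.na(d$pdi_min) & !is.na(d$is_day)))
})

test_that("LOESS trend smoothing is exact on lines and tracks known signals", {
  day <- seq(0, 80, length.out = 200)
  lin <- 25 - 0.1 * day
  fit <- trendSmooth(day, lin, nBoot = 20)
  expect_lt(max(abs(fit$fit - (25 - 0.1 * fit$day))), 1e-6)

  set.seed(9)
  y <- 20 + 3 * sin(day / 10) + rnorm(200, 0, 1.5)
  fit2 <- trendSmooth(day, y, span = 0.25, nBoot = 50, seed = 2)
  truth <- 20 + 3 * sin(fit2$day / 10)
  expect_lt(sqrt(mean((fit2$fit - truth)^2)), 1.5)
  expect_true(all(fit2$lwr <= fit2$upr))

  expect_error(trendSmooth(day[1:10], lin[1:10]), "at least 20")
  expect_error(trendSmooth(day, lin, span = 0.001), "span too small")
})

test_that("a declining-duration sick seal shows a declining fitted trend", {
  trip <- sickTrip()
  d <- diveData(trip@truthDives)
  day <- (d$start_time - trip@config@tripStart) / 86400
  fit <- trendSmooth(day, d$duration_min, span = 0.4, nBoot = 30)
  expect_lt(fit$fit[nrow(fit)], fit$fit[1])
})

test_that("LOESS agrees with the reference implementation on smooth data", {
  day <- seq(0, 10, length.out = 120)
  set.seed(10)
  y <- sin(day) + rnorm(120, 0, 0.2)
  ours <- trendSmooth(day, y, span = 0.5, nBoot = 10)
  ref <- predict(stats::loess(y ~ day, span = 0.5, degree = 1,
                              surface = "direct"),
                 newdata = data.frame(day = ours$day))
  expect_lt(max(abs(ours$fit - ref)), 0.1)
})
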