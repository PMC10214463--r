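# Fixture: a clean record of `n` identical trapezoid dives built directly
# (not via the generator), 8 s sampling.
trapezoidRecord <- function(nDives = 10, maxDepth = 400, rate = 1.25,
                            bottomSec = 600, surfaceSec = 120, dt = 8,
                            offset = 0) {
  oneDive <- c(seq(0, maxDepth, by = rate * dt),
               rep(maxDepth, bottomSec / dt),
               seq(maxDepth, 0, by = -rate * dt))
  surf <- rep(0, surfaceSec / dt)
  depth <- c(surf, rep(c(oneDive, surf), nDives))
  DepthRecord(seq(0, by = dt, length.out = length(depth)) + 1.5e9,
              depth + offset)
}

test_that("constant and linear sensor offsets are removed", {
  rec <- trapezoidRecord(nDives = 12, offset = 3)
  out <- zeroOffsetCorrect(rec, window = 30)
  clean <- depths(trapezoidRecord(nDives = 12, offset = 0))
  expect_lt(max(abs(depths(out$record) - clean)), 0.1)

  # linear drift 0 -> 1.5 m over ~4.6 h (same per-day slope scale as a
  # multi-day tag drifting several metres)
  rec2 <- trapezoidRecord(nDives = 12)
  drift <- seq(0, 1.5, length.out = length(rec2))
  rec2d <- DepthRecord(as.numeric(recordTime(rec2)), depths(rec2) + drift)
  out2 <- zeroOffsetCorrect(rec2d, window = 30)
  surface <- depths(rec2) == 0
  expect_lt(max(abs(depths(out2$record)[surface])), 0.5)

  # already-zeroed drift-free record passes through unchanged
  out3 <- zeroOffsetCorrect(trapezoidRecord(nDives = 12), window = 30)
  expect_equal(max(abs(depths(out3$record) -
                         depths(trapezoidRecord(nDives = 12)))), 0)

  expect_error(zeroOffsetCorrect(trapezoidRecord(nDives = 1), window = 300),
               "too short")
})

test_that("subsampling decimates on the native grid", {
  rec1 <- DepthRecord(1.5e9 + 0:799, sin(0:799 / 50) * 100 + 100)
  sub <- subsampleRecord(rec1, 8)
  expect_equal(sampleInterval(sub), 8)
  expect_equal(depths(sub), depths(rec1)[seq(1, 800, by = 8)])

  expect_identical(depths(subsampleRecord(sub, 8)), depths(sub))

  rec2 <- DepthRecord(1.5e9 + seq(0, by = 2, length.out = 100), rep(1, 100))
  expect_equal(length(subsampleRecord(rec2, 8)), 25)
  expect_error(subsampleRecord(rec2, 3), "integer multiple")
})

test_that("dive detection recovers injected dives and respects thresholds", {
  rec <- trapezoidRecord(nDives = 10)
  det <- detectDives(rec)
  expect_equal(nDives(det), 10)
  # boundaries within 1 sample of the true surface departures
  d <- diveData(det)
  expect_true(all(depths(rec)[d$start_idx] <= 2))
  expect_true(all(depths(rec)[d$end_idx] <= 2))

  flat <- DepthRecord(1.5e9 + seq(0, by = 8, length.out = 500), rep(0, 500))
  expect_equal(nDives(detectDives(flat)), 0)

  shallow <- trapezoidRecord(nDives = 1, maxDepth = 10)
  expect_equal(nDives(detectDives(shallow, minDepth = 15)), 0)
  expect_equal(nDives(detectDives(shallow, minDepth = 5)), 1)
})

test_that("detection matches the brute-force scan exactly", {
  trip <- simulateTrip(simConfig(seed = 31, tripDays = 1, noiseSd = 0.25,
                                 sensorOffsetStart = 0, sensorOffsetEnd = 0))
  rec <- trip@depthRecord
  expect_lte(length(rec), 11000)
  det <- diveData(detectDives(rec))
  ref <- bruteForceDives(depths(rec), sampleInterval(rec))
  expect_equal(nrow(det), nrow(ref))
  expect_equal(det$start_idx, ref[, 1])
  expect_equal(det$end_idx, ref[, 2])
})

test_that("raising the depth threshold never increases the dive count", {
  rec <- zeroOffsetCorrect(healthyTrip()@depthRecord)$record
  counts <- vapply(c(5, 15, 50, 200, 400, 600),
                   function(md) nDives(detectDives(rec, minDepth = md)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-dive statistics match closed forms on constructed profiles", {
  # triangular dive: descent 1.0 m/s to 300 m, ascent 1.5 m/s, 1 s sampling
  tri <- c(seq(0, 300, by = 1), seq(300 - 1.5, 0, by = -1.5))
  rec <- DepthRecord(1.5e9 + seq_along(c(0, tri, 0)) - 1, c(0, tri, 0))
  s <- diveStats(rec, 1, length(c(0, tri, 0)))
  expect_equal(s$duration_min * 60, 502, tolerance = 0.01)
  expect_equal(s$descent_rate, 1.0, tolerance = 0.01)
  expect_equal(s$ascent_rate, 1.5, tolerance = 0.01)
  # triangle spends (60 + 40) s at or below 0.8 * max
  expect_equal(s$bottom_time_min * 60, 100, tolerance = 2)
  expect_equal(s$max_depth, 300)

  # square dive with a 10-min flat bottom
  sq <- trapezoidRecord(nDives = 1, maxDepth = 500, bottomSec = 600,
                        rate = 12.5, dt = 8)
  d <- diveData(detectDives(sq))
  expect_equal(d$bottom_time_min, 10, tolerance = 0.3)

  # three sinusoidal bottom wiggles of 20 m amplitude
  bottom <- 500 - 10 + 10 * cos(2 * pi * 3 * seq(0, 1, length.out = 151) - pi)
  wig <- c(seq(0, 480, by = 10), bottom, seq(480, 0, by = -10))
  recW <- DepthRecord(1.5e9 + seq(0, by = 8, length.out = length(wig) + 2),
                      c(0, wig, 0))
  sW <- diveStats(recW, 1, length(wig) + 2)
  expect_equal(sW$n_wiggles, 3L)

  # degenerate two-sample dive flags and zeroes
  tiny <- DepthRecord(1.5e9 + 0:8, c(0, 20, 0, 0, 0, 0, 0, 0, 0), interval = 1)
  expect_warning(sD <- diveStats(tiny, 1, 2), "degenerate")
  expect_true(sD$flag_degenerate)
  expect_equal(sD$bottom_time_min, 0)
})

test_that("extended surface intervals are counted above the threshold", {
  pdis <- c(2, 2, 2, 2, NA)
  d <- diveData(healthyTrip()@truthDives)[1:5, ]
  d$pdi_min <- pdis
  tab <- DiveTable(d)
  expect_equal(extendedSurfaceIntervals(tab, 4)$count, 0)
  expect_equal(extendedSurfaceIntervals(tab, 0)$count, 4)

  sick <- sickTrip()
  dSick <- diveData(sick@truthDives)
  dayEnd <- floor((dSick$end_time - sick@config@tripStart) / 86400)
  inWin <- dayEnd >= 8 & dayEnd < 20 & !is.na(dSick$pdi_min)
  res <- extendedSurfaceIntervals(sick@truthDives, 3)
  expect_gte(res$count, sum(inWin))
  expect_error(extendedSurfaceIntervals(DiveTable(), 4), "empty")
})

test_that("dive durations, PDIs and surface margins tile the record span", {
  trip <- healthyTrip()
  rec <- zeroOffsetCorrect(trip@depthRecord)$record
  det <- detectDives(rec)
  d <- diveData(det)
  span <- diff(range(as.numeric(recordTime(rec))))
  lead <- d$start_time[1] - as.numeric(recordTime(rec))[1]
  trail <- as.numeric(recordTime(rec))[length(rec)] - d$end_time[nrow(d)]
  total <- sum(d$duration_min) * 60 + sum(d$pdi_min, na.rm = TRUE) * 60 +
    lead + trail
  expect_lt(abs(total - span), nrow(d) * sampleInterval(rec))
})

test_that("detected statistics track generator truth on a low-noise trip", {
  trip <- healthyTrip()
  det <- detectDives(zeroOffsetCorrect(trip@depthRecord)$record)
  m <- matchDives(trip@truthDives, det)
  td <- diveData(trip@truthDives); dd <- diveData(det)
  expect_gte(mean(abs(dd$start_time[m] - td$start_time) <= 16), 0.99)
  expect_gt(cor(dd$duration_min[m], td$duration_min), 0.999)
  expect_lt(max(abs(dd$max_depth[m] - td$max_depth)),
            3 * max(trip@config@noiseSd, 0.35))
})
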