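# Seeded synthetic-trip generator. Produces a depth series built from
# explicit dive cycles (so ground truth is known exactly), an hourly
# out-and-back track, jaw-motion events inside dive bottom phases, and a
# paired departure/arrival morphometry, under a healthy or sick regime.

# truncated log-normal (0.5 min floor) moment-matched to mean/sd, minutes
.rPdiHealthy <- function(n, mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmax(stats::rlnorm(n, meanlog, sdlog), 0.5)
}

.rLogUniform <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

.inIllness <- function(day, window) {
  length(window) == 2 && day >= window[1] && day < window[2]
}

#' Simulate a complete foraging trip
#'
#' Builds a trip dive-by-dive: trapezoidal depth profiles (constant-rate
#' descent and ascent, a bottom phase with sinusoidal wiggles reaching the
#' dive's maximum depth) separated by post-dive intervals drawn from the
#' regime active on that trip day. Healthy PDIs are truncated log-normal
#' around `pdiMean`; inside `illnessWindow` they are log-uniform on
#' `illnessPdiRange`; after the window each dive has probability
#' `lateExtendedPdiProb` of a log-uniform `lateExtendedPdiRange` PDI. Linear
#' sensor drift and Gaussian noise are added last, so the returned truth
#' table records the uncorrupted dive start/end/depth/duration/PDI. Day
#' dives are deeper than night dives (diel modulation via solar elevation at
#' the colony longitude).
#'
#' @param config a [SimConfig-class].
#' @return A [SimulatedTrip-class]. Deterministic for a fixed seed.
#' @examples
#' trip <- simulateTrip(simConfig(seed = 1, tripDays = 2))
#' trip
#' @export
simulateTrip <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  dt <- config@sampleInterval
  dr <- config@descentRate
  ar <- config@ascentRate
  travelPerM <- 1 / dr + 1 / ar
  meanDepth <- (config@diveDepthDayMean + config@diveDepthNightMean) / 2
  if (config@diveDurationMean * 60 <= meanDepth * travelPerM)
    stop("mean dive duration (", config@diveDurationMean,
         " min) is shorter than achievable at the mean depth and ",
         "descent/ascent rates")

  set.seed(config@seed)
  t0 <- config@tripStart
  tEnd <- t0 + config@tripDays * 86400

  ts <- te <- zmax <- dur <- bt <- pdi <- numeric(0)
  nwig <- integer(0)
  profile <- list()   # per-dive (td, Tb, ta, depthShoulder, A, nwig)

  tc <- t0 + .rPdiHealthy(1, config@pdiMean, config@pdiSd) * 60
  repeat {
    day <- floor((tc - t0) / 86400)
    isDay <- solarElevation(tc, config@colonyLatLon[1],
                            config@colonyLatLon[2]) > 0
    depthMean <- if (isDay) config@diveDepthDayMean else config@diveDepthNightMean
    Z <- stats::rnorm(1, depthMean, config@diveDepthSd)
    Z <- min(max(Z, 100), 1100)
    Dmin <- (100 * travelPerM + 60) / 60
    D <- stats::rnorm(1, config@diveDurationMean + config@diveDurationTrend * day,
                      config@diveDurationSd)
    D <- min(max(D, Dmin), 90)
    # guarantee >= 60 s of bottom time by shallowing the dive if needed
    Z <- min(Z, (D * 60 - 60) / travelPerM)
    if (tc + D * 60 > tEnd) break

    Tb0 <- D * 60 - Z * travelPerM
    nw <- stats::rpois(1, config@wiggleRate * Tb0 / 60)
    nw <- min(nw, floor(Tb0 / (6 * dt)))       # keep wiggle period resolvable
    A <- if (nw > 0) min(20, 0.15 * Z) else 0
    shoulder <- Z - A                          # depth where bottom phase begins
    td <- shoulder / dr
    ta <- shoulder / ar
    Tb <- D * 60 - td - ta

    dayEnd <- floor((tc + D * 60 - t0) / 86400)
    p <- if (.inIllness(dayEnd, config@illnessWindow)) {
      .rLogUniform(1, config@illnessPdiRange[1], config@illnessPdiRange[2])
    } else if (length(config@illnessWindow) == 2 &&
               dayEnd >= config@illnessWindow[2] &&
               stats::runif(1) < config@lateExtendedPdiProb) {
      .rLogUniform(1, config@lateExtendedPdiRange[1],
                   config@lateExtendedPdiRange[2])
    } else {
      .rPdiHealthy(1, config@pdiMean, config@pdiSd)
    }

    k <- length(ts) + 1L
    ts[k] <- tc; te[k] <- tc + D * 60; dur[k] <- D
    bt[k] <- Tb / 60; nwig[k] <- nw; pdi[k] <- p; zmax[k] <- Z
    profile[[k]] <- c(td = td, Tb = Tb, ta = ta, shoulder = shoulder,
                      A = A, nw = nw)
    tc <- te[k] + p * 60
  }
  if (!length(ts)) stop("no dives fit inside the trip; check the config")
  pdi[length(pdi)] <- NA_real_   # last dive has no successor

  # sample grid and clean depth series
  times <- seq(t0, tEnd, by = dt)
  N <- length(times)
  depth <- numeric(N)
  sampledMax <- numeric(length(ts))
  for (k in seq_along(ts)) {
    i1 <- ceiling((ts[k] - t0) / dt) + 1L
    i2 <- floor((te[k] - t0) / dt) + 1L
    if (i2 < i1) { sampledMax[k] <- 0; next }
    u <- times[i1:i2] - ts[k]
    pr <- profile[[k]]
    d <- numeric(length(u))
    desc <- u <= pr["td"]
    bot <- u > pr["td"] & u <= pr["td"] + pr["Tb"]
    asc <- u > pr["td"] + pr["Tb"]
    d[desc] <- dr * u[desc]
    if (pr["nw"] > 0) {
      ub <- u[bot] - pr["td"]
      d[bot] <- zmax[k] - pr["A"] / 2 -
        (pr["A"] / 2) * cos(2 * pi * pr["nw"] * ub / pr["Tb"])
    } else d[bot] <- zmax[k]
    d[asc] <- pr["shoulder"] - ar * (u[asc] - pr["td"] - pr["Tb"])
    d <- pmax(d, 0)
    depth[i1:i2] <- d
    sampledMax[k] <- max(d)
  }

  # corrupt: linear sensor drift plus Gaussian noise
  offs <- seq(config@sensorOffsetStart, config@sensorOffsetEnd,
              length.out = N)
  raw <- depth + offs + stats::rnorm(N, 0, config@noiseSd)
  record <- new("DepthRecord", time = times, depth = raw, interval = dt)

  # truth table uses the uncorrupted series: max depth is the clean sampled
  # maximum, times are the analytic dive boundaries
  truth <- DiveTable(data.frame(
    start_idx = as.integer(ceiling((ts - t0) / dt) + 1L),
    end_idx = as.integer(floor((te - t0) / dt) + 1L),
    start_time = ts, end_time = te, max_depth = sampledMax,
    duration_min = dur, bottom_time_min = bt, n_wiggles = nwig,
    descent_rate = dr, ascent_rate = ar, pdi_min = pdi,
    is_day = NA, lat = NA_real_, lon = NA_real_))

  track <- .simulateTrack(config, t0, tEnd)
  events <- simulateJawEvents(config, truth)
  morpho <- list(departure = syntheticMorphometry(294, 0.247, "departure"),
                 arrival = syntheticMorphometry(245, 0.183, "arrival"))

  new("SimulatedTrip", depthRecord = record, truthDives = truth,
      track = track, jawEvents = events, morphometryPair = morpho,
      config = config)
}

# Out-and-back persistent random walk from the colony at hourly fixes;
# downstream consumers only use distances and time-interpolation, so a simple
# kinematic walk suffices.
.simulateTrack <- function(config, t0, tEnd) {
  tt <- seq(t0, tEnd, by = 3600)
  nH <- length(tt)
  stepKm <- config@dailyDisplacement / 24
  lat <- lon <- numeric(nH)
  lat[1] <- config@colonyLatLon[1]
  lon[1] <- config@colonyLatLon[2]
  baseBearing <- stats::runif(1, 180, 300)   # broadly offshore (W-SW)
  noise <- stats::rnorm(nH, 0, 15)
  half <- nH %/% 2
  for (i in seq_len(nH - 1)) {
    if (i <= half) {
      brg <- baseBearing + noise[i]
    } else {
      # head home: bearing towards the colony
      dy <- config@colonyLatLon[1] - lat[i]
      dx <- (config@colonyLatLon[2] - lon[i]) * cos(lat[i] * pi / 180)
      brg <- atan2(dx, dy) * 180 / pi + noise[i]
    }
    lat[i + 1] <- lat[i] + stepKm * cos(brg * pi / 180) / 111.195
    lon[i + 1] <- lon[i] + stepKm * sin(brg * pi / 180) /
      (111.195 * cos(lat[i] * pi / 180))
    lat[i + 1] <- min(max(lat[i + 1], -89), 89)
  }
  Track(tt, lat, lon)
}

#' Simulate jaw-motion (prey-capture-attempt) events
#'
#' Draws a Poisson daily event count at the regime rate (healthy outside the
#' illness window, sick inside it) and places the events uniformly within
#' the bottom phases of that day's dives. Days whose dives have no bottom
#' time get zero events. Uses its own seed stream (derived from
#' `config@seed`) so the same events result whether called standalone or
#' from [simulateTrip()].
#'
#' @param config a [SimConfig-class].
#' @param truthDives a nonempty [DiveTable-class] (generator ground truth).
#' @return Sorted numeric epoch seconds of events, all inside dive bottom
#'   phases.
#' @export
simulateJawEvents <- function(config, truthDives) {
  stopifnot(is(config, "SimConfig"), is(truthDives, "DiveTable"))
  d <- diveData(truthDives)
  if (!nrow(d)) stop("truthDives must be nonempty")
  set.seed(config@seed + 104729L)
  t0 <- config@tripStart
  # bottom phase from table columns: travel time splits descent:ascent as
  # ar:dr, so descent time = (duration - bottom) * ar / (ar + dr)
  travel <- (d$duration_min - d$bottom_time_min) * 60
  tdesc <- travel * d$ascent_rate / (d$ascent_rate + d$descent_rate)
  bs <- d$start_time + tdesc
  be <- bs + d$bottom_time_min * 60
  events <- numeric(0)
  for (day in 0:(ceiling(config@tripDays) - 1)) {
    w0 <- t0 + day * 86400; w1 <- w0 + 86400
    rate <- if (.inIllness(day, config@illnessWindow))
      config@eventsPerDaySick else config@eventsPerDayHealthy
    n <- stats::rpois(1, rate)
    if (n == 0) next
    s <- pmax(bs, w0); e <- pmin(be, w1)
    ok <- which(e > s)
    if (!length(ok)) next
    len <- e[ok] - s[ok]
    cum <- cumsum(len)
    pos <- stats::runif(n, 0, cum[length(cum)])
    j <- findInterval(pos, c(0, cum[-length(cum)]))
    events <- c(events, s[ok][j] + (pos - c(0, cum[-length(cum)])[j]))
  }
  sort(events)
}

#' Build a synthetic morphometry record with known composition
#'
#' Constructs a plausible seal of the requested mass and adipose fraction:
#' girths follow a fusiform relative profile scaled so the best-variant
#' truncated-cones volume matches `mass / bodyDensity`, and blubber
#' thicknesses are solved (uniroot on a station-shaped thickness profile) so
#' the blubber-shell adipose fraction equals `adiposeFraction` under the
#' identity calibration. Deterministic; labelled synthetic.
#'
#' @param massKg body mass, kg.
#' @param adiposeFraction target adipose fraction.
#' @param stage `"departure"` or `"arrival"`.
#' @param standardLength cm (default 253).
#' @param fastingDays days fasting before the measurement (default 2).
#' @param bodyDensity whole-body density, kg/m^3 (default 1030).
#' @return A [MorphometryRecord-class] whose [adiposeFromCones()] raw
#'   fraction equals the target.
#' @export
syntheticMorphometry <- function(massKg, adiposeFraction,
                                 stage = c("departure", "arrival"),
                                 standardLength = 253, fastingDays = 2,
                                 bodyDensity = 1030) {
  stage <- match.arg(stage)
  relGirth <- c(0.62, 0.88, 1.00, 0.97, 0.82, 0.58)
  thickShape <- c(0.9, 1.05, 1.10, 1.05, 0.95, 0.85)
  m0 <- MorphometryRecord(massKg, standardLength, relGirth * 160,
                          blubberDorsal = rep(0.1, 6),
                          blubberLateral = rep(0.1, 6),
                          fastingDays = fastingDays, stage = stage)
  v0 <- bodySAV(m0, "best")$volume
  scale <- sqrt((massKg / bodyDensity) / v0)
  girths <- relGirth * 160 * scale

  mk <- function(tcm) MorphometryRecord(massKg, standardLength, girths,
                                        blubberDorsal = 1.05 * tcm * thickShape,
                                        blubberLateral = 0.95 * tcm * thickShape,
                                        fastingDays = fastingDays, stage = stage)
  # feasibility bound includes the unmeasured ear/ankle boundary radii
  radCm <- girths / (2 * pi)
  effRad <- c(0.70 * radCm[1], radCm, 0.60 * radCm[6])
  effShape <- c(thickShape[1], thickShape, thickShape[6])
  f <- function(tcm) adiposeFromCones(mk(tcm))$raw_fraction - adiposeFraction
  sol <- stats::uniroot(f, c(1e-4, 0.9 * min(effRad / effShape)),
                        tol = 1e-10)
  mk(sol$root)
}
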