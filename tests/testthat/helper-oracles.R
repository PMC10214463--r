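# Independent oracles and small fixtures used across the suite. Each oracle
# is deliberately implemented from a different formulation than the package
# code it checks.

# Astronomical Almanac low-precision solar position (RA/decl + sidereal
# time), independent of the package's NOAA calculator series.
almanacElevation <- function(time, lat, lon) {
  n <- as.numeric(time) / 86400 + 2440587.5 - 2451545
  deg <- pi / 180
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * deg) + 0.020 * sin(2 * g * deg)
  eps <- 23.439 - 0.0000004 * n
  decl <- asin(sin(eps * deg) * sin(lam * deg))
  ra <- atan2(cos(eps * deg) * sin(lam * deg), cos(lam * deg))
  gmst <- (18.697374558 + 24.06570982441908 * n) %% 24
  ha <- (gmst * 15 + lon) * deg - ra
  cosz <- sin(lat * deg) * sin(decl) + cos(lat * deg) * cos(decl) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cosz))) / deg
}

# Spherical law of cosines distance, R = 6371 km.
lawOfCosinesKm <- function(lat1, lon1, lat2, lon2) {
  deg <- pi / 180
  cosd <- sin(lat1 * deg) * sin(lat2 * deg) +
    cos(lat1 * deg) * cos(lat2 * deg) * cos((lon2 - lon1) * deg)
  6371 * acos(pmin(1, pmax(-1, cosd)))
}

# Brute-force dive detection: explicit sample scan over threshold crossings,
# same contract as detectDives (bracketing samples, depth and duration
# thresholds) but written as a plain loop.
bruteForceDives <- function(depth, dt, minDepth = 15, minDuration = 32,
                            surfaceThreshold = 2) {
  n <- length(depth)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (depth[i] > surfaceThreshold) {
      j <- i
      while (j < n && depth[j + 1L] > surfaceThreshold) j <- j + 1L
      s0 <- max(1L, i - 1L)
      e0 <- min(n, j + 1L)
      if ((e0 - s0) * dt >= minDuration && max(depth[i:j]) >= minDepth)
        out <- rbind(out, c(s0, e0))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# Frustum solid of revolution by numerical quadrature (r linear in z).
frustumNumeric <- function(r1, r2, h) {
  r <- function(z) r1 + (r2 - r1) * z / h
  slant <- sqrt(1 + ((r2 - r1) / h)^2)
  list(volume = stats::integrate(function(z) pi * r(z)^2, 0, h,
                                 rel.tol = 1e-13)$value,
       lateral_area = stats::integrate(function(z) 2 * pi * r(z) * slant,
                                       0, h, rel.tol = 1e-13)$value)
}

# Direct kernel-sum 2-D Gaussian density at arbitrary nodes.
kdeDirect <- function(px, py, x, y, hx, hy) {
  vapply(seq_along(px), function(i) {
    mean(stats::dnorm((px[i] - x) / hx) / hx *
           stats::dnorm((py[i] - y) / hy) / hy)
  }, numeric(1))
}

# Nearest-start matching of detected dives to truth dives.
matchDives <- function(truth, detected) {
  td <- diveData(truth)
  dd <- diveData(detected)
  vapply(td$start_time, function(s) which.min(abs(dd$start_time - s)),
         integer(1))
}

# Small shared trips (built once per test run).
healthyTrip <- local({
  trip <- NULL
  function() {
    if (is.null(trip))
      trip <<- simulateTrip(simConfig(seed = 101, tripDays = 10,
                                      sensorOffsetStart = 0,
                                      sensorOffsetEnd = 3))
    trip
  }
})

sickTrip <- local({
  trip <- NULL
  function() {
    if (is.null(trip))
      trip <<- simulateTrip(simConfig(seed = 102, tripDays = 25,
                                      illnessWindow = c(8, 20),
                                      lateExtendedPdiProb = 0.02,
                                      diveDurationTrend = -0.15))
    trip
  }
})
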