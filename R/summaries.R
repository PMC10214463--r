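# Trip-level summaries: Table-style trip report, 2-D kernel densities,
# cumulative PDI curves and day-of-trip trend smoothing.

.meanSd <- function(x) {
  x <- x[!is.na(x)]
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
}

#' Trip summary report
#'
#' Computes the standard trip metrics from the processed stages: corrected
#' mass gain and its energy equivalent, trip duration, total and maximum
#' distances, dive counts, the extended-PDI count, and grand means +/- SD of
#' the diving statistics overall and split by day/night (located dives
#' only). Measured masses are moved to the at-sea endpoints with the fasting
#' correction: departure mass = measured - correction (the animal keeps
#' fasting between measurement and departure), arrival mass = measured +
#' correction.
#'
#' @param dives a [DiveTable-class] after [classifyDayNight()].
#' @param track an interpolated [Track-class].
#' @param morphoPair list with `departure` and `arrival`
#'   [MorphometryRecord-class] objects.
#' @param events optional event timestamps (adds foraging metrics).
#' @param colony `c(lat, lon)`; defaults to the first track fix.
#' @param adiposeFractions optional `c(departure, arrival)` fractions to use
#'   instead of the blubber-shell estimate.
#' @param constants an [EnergyConstants-class].
#' @param pdiThreshold minutes for the extended-PDI count (default 4).
#' @return A [TripSummary-class].
#' @export
tripSummary <- function(dives, track, morphoPair, events = NULL,
                        colony = NULL, adiposeFractions = NULL,
                        constants = energyConstants(), pdiThreshold = 4) {
  stopifnot(is(dives, "DiveTable"), is(track, "Track"))
  if (is.null(morphoPair$departure) || is.null(morphoPair$arrival))
    stop("morphoPair must have stages 'departure' and 'arrival'")
  d <- diveData(dives)
  if (!nrow(d)) stop("stage 'dive detection' produced no dives")
  if (is.null(colony)) colony <- c(track@lat[1], track@lon[1])

  dep <- morphoPair$departure; arr <- morphoPair$arrival
  depMass <- dep@mass - massCorrectionBreed(dep@mass, dep@fastingDays)
  arrMass <- arr@mass + massCorrectionBreed(arr@mass, arr@fastingDays)
  fracDep <- if (!is.null(adiposeFractions)) adiposeFractions[1] else
    adiposeFromCones(dep)$fraction
  fracArr <- if (!is.null(adiposeFractions)) adiposeFractions[2] else
    adiposeFromCones(arr)$fraction
  sDep <- compositionSplit(depMass, fracDep)
  sArr <- compositionSplit(arrMass, fracArr)
  gainE <- tissueEnergy(sArr$ffm_raw_kg - sDep$ffm_raw_kg,
                        sArr$adipose_raw_kg - sDep$adipose_raw_kg, constants)

  dist <- tripDistances(track, colony)
  days <- (track@time[length(track@time)] - track@time[1]) / 86400
  located <- !is.na(d$is_day)

  splitStats <- function(col) {
    list(all = .meanSd(d[[col]]),
         day = .meanSd(d[[col]][located & d$is_day]),
         night = .meanSd(d[[col]][located & !d$is_day]))
  }
  metrics <- list(
    trip_duration_days = days,
    mass_gain_kg = arrMass - depMass,
    mass_gain_rate_kg_day = (arrMass - depMass) / days,
    energy_gain_MJ = gainE$total_MJ,
    energy_gain_rate_MJ_day = gainE$total_MJ / days,
    departure_mass_kg = depMass, arrival_mass_kg = arrMass,
    departure_adipose_pct = 100 * fracDep,
    arrival_adipose_pct = 100 * fracArr,
    total_distance_km = dist$total_km,
    max_distance_km = dist$max_from_colony_km,
    n_dives = nrow(d),
    n_located_dives = sum(located),
    n_day_dives = sum(located & d$is_day),
    n_night_dives = sum(located & !d$is_day),
    n_pdi_gt_threshold = extendedSurfaceIntervals(dives, pdiThreshold)$count,
    pdi_threshold_min = pdiThreshold,
    max_depth_m = splitStats("max_depth"),
    duration_min = splitStats("duration_min"),
    bottom_time_min = splitStats("bottom_time_min"),
    descent_rate_ms = splitStats("descent_rate"),
    ascent_rate_ms = splitStats("ascent_rate"),
    pdi_min = splitStats("pdi_min"))

  if (!is.null(events)) {
    epd <- eventsPerDay(events, tripStart = d$start_time[1])
    metrics$events_per_day <- .meanSd(epd$count)
    metrics$pct_time_foraging <- percentTimeForaging(events, dives)$trip_pct
  }
  new("TripSummary", metrics = metrics)
}

#' Two-dimensional Gaussian kernel density
#'
#' Product Gaussian kernel on a regular grid, with per-axis bandwidths from
#' Scott's rule for two dimensions (`sd * n^(-1/6)`) by default. The grid
#' extends `cut` bandwidths beyond the data range so the surface integrates
#' to 1 over the grid (within 1%). Used for dive (depth, duration) and
#' (duration, PDI) density contours.
#'
#' @param x,y numeric vectors (>= 10 points each).
#' @param bandwidth numeric `c(hx, hy)`; default Scott's rule.
#' @param gridSize points per axis (default 64).
#' @param cut grid margin in bandwidths (default 4).
#' @return List with `x`, `y` (grid vectors), `z` (density matrix,
#'   `gridSize` x `gridSize`) and `bandwidth`.
#' @export
diveKDE2d <- function(x, y, bandwidth = NULL, gridSize = 64, cut = 4) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 points")
  if (is.null(bandwidth))
    bandwidth <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
    stop("degenerate (zero-variance) axis")
  hx <- bandwidth[1]; hy <- bandwidth[2]
  gx <- seq(min(x) - cut * hx, max(x) + cut * hx, length.out = gridSize)
  gy <- seq(min(y) - cut * hy, max(y) + cut * hy, length.out = gridSize)
  Ax <- stats::dnorm(outer(gx, x, "-") / hx) / hx
  Ay <- stats::dnorm(outer(gy, y, "-") / hy) / hy
  list(x = gx, y = gy, z = Ax %*% t(Ay) / n, bandwidth = c(hx, hy))
}

#' Cumulative distribution of post-dive intervals
#'
#' Empirical CDF of PDI durations, optionally split day/night, with an
#' optional zoom into the top quantile band (where the extended surface
#' intervals of a sick animal separate from healthy records).
#'
#' @param pdis PDI durations in minutes (`NA` dropped).
#' @param isDay optional logical of the same length; splits the curve.
#' @param topQuantile if given (e.g. 0.98), only the part of each curve with
#'   CDF >= this value is returned.
#' @return data.frame with `split` (`"all"`, `"day"`, `"night"`), `pdi_min`
#'   (sorted) and `cdf`.
#' @export
cumulativePdiCurve <- function(pdis, isDay = NULL, topQuantile = NULL) {
  keep <- !is.na(pdis)
  if (!is.null(isDay)) keep <- keep & !is.na(isDay)
  pdis <- pdis[keep]
  if (!length(pdis)) stop("no PDIs")
  groups <- if (is.null(isDay)) list(all = pdis) else {
    isDay <- isDay[keep]
    list(day = pdis[isDay], night = pdis[!isDay])
  }
  out <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- sort(groups[[nm]])
    if (!length(v)) return(NULL)
    data.frame(split = nm, pdi_min = v, cdf = seq_along(v) / length(v))
  }))
  if (!is.null(topQuantile)) out <- out[out$cdf >= topQuantile, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Local linear regression with tricube weights at the q = ceiling(span * n)
# nearest neighbours (classic LOESS, degree 1). Exact on linear data.
.localLinear <- function(x, y, xout, span) {
  n <- length(x)
  q <- max(4L, min(n, as.integer(ceiling(span * n))))
  vapply(xout, function(g) {
    dist <- abs(x - g)
    h <- sort(dist, partial = q)[q]
    if (h <= 0) return(mean(y[dist == 0]))
    w <- (1 - pmin(dist / h, 1)^3)^3
    xc <- x - g
    Sw <- sum(w); Sx <- sum(w * xc); Sxx <- sum(w * xc^2)
    Sy <- sum(w * y); Sxy <- sum(w * xc * y)
    den <- Sw * Sxx - Sx^2
    if (abs(den) < 1e-12 * max(Sw * Sxx, 1e-300)) return(Sy / Sw)
    (Sxx * Sy - Sx * Sxy) / den
  }, numeric(1))
}

#' Day-of-trip trend smoothing
#'
#' LOESS (local linear, tricube weights) fitted over day of trip, with a
#' seeded bootstrap pointwise confidence band. Used to recover trends such
#' as a declining dive duration across a trip.
#'
#' @param day numeric day-of-trip (or any predictor), >= 20 points.
#' @param y response.
#' @param span LOESS span (fraction of points in each local fit, default
#'   0.3). `span * n` must be at least 4.
#' @param nBoot bootstrap resamples for the band (default 200).
#' @param level band level (default 0.95).
#' @param seed bootstrap seed (default 1).
#' @param gridN evaluation grid size (default 80).
#' @return data.frame with `day`, `fit`, `lwr`, `upr`.
#' @export
trendSmooth <- function(day, y, span = 0.3, nBoot = 200, level = 0.95,
                        seed = 1, gridN = 80) {
  ok <- is.finite(day) & is.finite(y)
  day <- day[ok]; y <- y[ok]
  n <- length(day)
  if (n < 20) stop("need at least 20 points")
  if (span * n < 4) stop("span too small for data density")
  grid <- seq(min(day), max(day), length.out = gridN)
  fit <- .localLinear(day, y, grid, span)
  boots <- matrix(NA_real_, nBoot, gridN)
  set.seed(seed)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- .localLinear(day[idx], y[idx], grid, span)
  }
  a <- (1 - level) / 2
  data.frame(day = grid, fit = fit,
             lwr = apply(boots, 2, stats::quantile, a, na.rm = TRUE),
             upr = apply(boots, 2, stats::quantile, 1 - a, na.rm = TRUE))
}
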