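#' @import methods
NULL

.isoFormat <- "%Y-%m-%dT%H:%M:%SZ"

.asEpoch <- function(x) {
  if (inherits(x, "POSIXt")) return(as.numeric(x))
  if (is.character(x)) {
    out <- as.numeric(as.POSIXct(x, tz = "UTC",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                                "%Y-%m-%dT%H:%M:%OS",
                                                "%Y-%m-%d %H:%M:%OS",
                                                "%Y-%m-%d")))
    if (anyNA(out)) stop("unparseable timestamp(s)")
    return(out)
  }
  as.numeric(x)
}

.asUTC <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

#' Regularly sampled depth time series
#'
#' `DepthRecord` holds a time-depth-recorder (TDR) record: a strictly
#' increasing, regularly sampled depth series (metres, positive down) with its
#' sampling interval in seconds. It is the raw substrate for zero-offset
#' correction and dive detection.
#'
#' @slot time numeric, seconds since the UNIX epoch (UTC), strictly increasing
#'   and regular.
#' @slot depth numeric, depth in metres (positive down), finite.
#' @slot interval numeric scalar, sampling interval in seconds.
#' @export
setClass("DepthRecord",
  representation(time = "numeric", depth = "numeric", interval = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@time) != length(object@depth))
      msg <- c(msg, "time and depth must have equal length")
    if (length(object@time) >= 2) {
      dt <- diff(object@time)
      if (any(dt <= 0)) msg <- c(msg, "timestamps must be strictly increasing")
      # regular within 1 ms
      if (max(abs(dt - object@interval)) > 1e-3)
        msg <- c(msg, "sampling must be regular within 1 ms of the stated interval")
    }
    if (length(object@interval) != 1 || object@interval <= 0)
      msg <- c(msg, "interval must be a positive scalar")
    if (any(!is.finite(object@depth))) msg <- c(msg, "depths must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a DepthRecord
#'
#' @param time timestamps (POSIXct, ISO-8601 strings, or numeric epoch
#'   seconds), strictly increasing and regularly spaced.
#' @param depth numeric depths in metres, positive down.
#' @param interval sampling interval in seconds; inferred from `time` when
#'   omitted.
#' @return A [DepthRecord-class] object.
#' @examples
#' rec <- DepthRecord(seq(0, 80, by = 8), c(0, 5, 20, 80, 120, 120, 80, 20, 5, 0, 0))
#' sampleInterval(rec)
#' @export
DepthRecord <- function(time, depth, interval = NULL) {
  t <- .asEpoch(time)
  if (is.null(interval)) {
    if (length(t) < 2) stop("need at least two samples to infer the interval")
    interval <- stats::median(diff(t))
  }
  new("DepthRecord", time = t, depth = as.numeric(depth),
      interval = as.numeric(interval))
}

#' Table of detected (or simulated) dives
#'
#' One row per dive with the standard per-dive statistics: start/end sample
#' indices and times, maximum depth (m), duration (min), bottom time (min),
#' wiggle count, descent/ascent rates (m/s), post-dive interval (min, `NA` for
#' the last dive), and the day/night flag and interpolated location filled in
#' by [classifyDayNight()].
#'
#' @slot dives data.frame with the fixed column set documented in
#'   [diveData()].
#' @export
setClass("DiveTable",
  representation(dives = "data.frame"),
  validity = function(object) {
    d <- object@dives
    need <- c("start_idx", "end_idx", "start_time", "end_time", "max_depth",
              "duration_min", "bottom_time_min", "n_wiggles", "descent_rate",
              "ascent_rate", "pdi_min", "is_day", "lat", "lon")
    if (!all(need %in% names(d)))
      return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
    if (nrow(d) >= 2) {
      if (is.unsorted(d$start_time)) return("dives must be time-ordered")
      if (any(d$start_time[-1] < d$end_time[-nrow(d)]))
        return("dives must not overlap")
    }
    if (any(d$duration_min <= 0)) return("durations must be positive")
    if (any(d$pdi_min < 0, na.rm = TRUE)) return("PDIs must be non-negative")
    TRUE
  }
)

.emptyDiveFrame <- function() {
  data.frame(start_idx = integer(0), end_idx = integer(0),
             start_time = numeric(0), end_time = numeric(0),
             max_depth = numeric(0), duration_min = numeric(0),
             bottom_time_min = numeric(0), n_wiggles = integer(0),
             descent_rate = numeric(0), ascent_rate = numeric(0),
             pdi_min = numeric(0), is_day = logical(0),
             lat = numeric(0), lon = numeric(0),
             flag_degenerate = logical(0))
}

#' Construct a DiveTable from a data.frame
#'
#' @param dives data.frame with (at least) the columns listed in
#'   [DiveTable-class]; missing optional columns (`is_day`, `lat`, `lon`,
#'   `flag_degenerate`) are filled with `NA`/`FALSE`.
#' @return A [DiveTable-class] object.
#' @export
DiveTable <- function(dives = .emptyDiveFrame()) {
  if (!nrow(dives)) return(new("DiveTable", dives = .emptyDiveFrame()))
  if (is.null(dives$is_day)) dives$is_day <- NA
  if (is.null(dives$lat)) dives$lat <- NA_real_
  if (is.null(dives$lon)) dives$lon <- NA_real_
  if (is.null(dives$flag_degenerate)) dives$flag_degenerate <- FALSE
  rownames(dives) <- NULL
  new("DiveTable", dives = dives)
}

#' Location track
#'
#' Time-ordered sequence of geographic fixes (decimal degrees, WGS-84),
#' assumed already quality-filtered.
#'
#' @slot time numeric epoch seconds (UTC), non-decreasing.
#' @slot lat,lon numeric decimal degrees.
#' @export
setClass("Track",
  representation(time = "numeric", lat = "numeric", lon = "numeric"),
  validity = function(object) {
    if (length(object@time) != length(object@lat) ||
        length(object@time) != length(object@lon))
      return("time, lat, lon must have equal length")
    if (any(abs(object@lat) > 90)) return("|lat| must be <= 90")
    if (any(abs(object@lon) > 180)) return("|lon| must be <= 180")
    if (is.unsorted(object@time)) return("track must be time-ordered")
    TRUE
  }
)

#' Construct a Track
#' @param time timestamps (POSIXct, ISO strings or epoch seconds).
#' @param lat,lon decimal degrees.
#' @return A [Track-class] object.
#' @export
Track <- function(time, lat, lon) {
  new("Track", time = .asEpoch(time), lat = as.numeric(lat),
      lon = as.numeric(lon))
}

#' One sedation's body measurements
#'
#' Mass, standard length, girths at six axial stations, paired dorsal/lateral
#' blubber thicknesses at the same stations, and the number of days the animal
#' fasted on shore between the at-sea endpoint and the measurement.
#'
#' @slot mass kg. @slot standardLength cm.
#' @slot stationPositions six axial fractions of standard length (from the
#'   nose), ordered increasing.
#' @slot girths cm at the six stations.
#' @slot blubberDorsal,blubberLateral cm at the six stations.
#' @slot fastingDays days fasting on shore before/after the measurement.
#' @slot stage `"departure"` or `"arrival"`.
#' @export
setClass("MorphometryRecord",
  representation(mass = "numeric", standardLength = "numeric",
                 stationPositions = "numeric", girths = "numeric",
                 blubberDorsal = "numeric", blubberLateral = "numeric",
                 fastingDays = "numeric", stage = "character"),
  validity = function(object) {
    msg <- character(0)
    if (object@mass <= 0) msg <- c(msg, "mass must be positive")
    if (object@standardLength <= 0) msg <- c(msg, "standard length must be positive")
    for (nm in c("stationPositions", "girths", "blubberDorsal", "blubberLateral"))
      if (length(slot(object, nm)) != 6)
        msg <- c(msg, paste(nm, "must have 6 values"))
    if (any(object@girths <= 0, na.rm = TRUE)) msg <- c(msg, "girths must be positive")
    if (any(c(object@blubberDorsal, object@blubberLateral) < 0, na.rm = TRUE))
      msg <- c(msg, "blubber thicknesses must be non-negative")
    if (is.unsorted(object@stationPositions, strictly = TRUE))
      msg <- c(msg, "station positions must be strictly increasing")
    if (object@fastingDays < 0) msg <- c(msg, "fasting days must be non-negative")
    if (!object@stage %in% c("departure", "arrival"))
      msg <- c(msg, "stage must be 'departure' or 'arrival'")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a MorphometryRecord
#'
#' @param mass body mass, kg.
#' @param standardLength nose-to-tail standard length, cm.
#' @param girths girths (cm) at the six measurement stations.
#' @param blubberDorsal,blubberLateral blubber thickness (cm) at the six
#'   stations along the dorsal and lateral lines.
#' @param stationPositions axial positions of the stations as fractions of
#'   standard length from the nose; default six evenly spaced locations.
#' @param fastingDays days fasting on shore between the at-sea endpoint and
#'   the measurement (used by the mass correction).
#' @param stage `"departure"` or `"arrival"`.
#' @return A [MorphometryRecord-class] object.
#' @export
MorphometryRecord <- function(mass, standardLength, girths,
                              blubberDorsal, blubberLateral,
                              stationPositions = (1:6) / 7,
                              fastingDays = 0,
                              stage = c("departure", "arrival")) {
  stage <- match.arg(stage)
  new("MorphometryRecord", mass = as.numeric(mass),
      standardLength = as.numeric(standardLength),
      stationPositions = as.numeric(stationPositions),
      girths = as.numeric(girths),
      blubberDorsal = as.numeric(blubberDorsal),
      blubberLateral = as.numeric(blubberLateral),
      fastingDays = as.numeric(fastingDays), stage = stage)
}

#' Derived body composition
#'
#' Adipose fraction and masses plus the truncated-cones surface area, volume,
#' and SA/V under the three geometric variants (best / min / max).
#'
#' @slot adiposeFraction unitless in `[0, 1]`.
#' @slot adiposeKg,ffmKg kg (integer-kg reporting; raw values in `raw`).
#' @slot surfaceArea m^2 (best variant). @slot volume m^3 (best variant).
#' @slot savr named numeric, m^-1, names `best`, `min`, `max`.
#' @slot raw named numeric carrying unrounded adipose/FFM masses.
#' @export
setClass("BodyComposition",
  representation(adiposeFraction = "numeric", adiposeKg = "numeric",
                 ffmKg = "numeric", surfaceArea = "numeric",
                 volume = "numeric", savr = "numeric", raw = "numeric"),
  validity = function(object) {
    if (object@adiposeFraction < 0 || object@adiposeFraction > 1)
      return("adipose fraction must be in [0, 1]")
    if (all(c("min", "best", "max") %in% names(object@savr))) {
      s <- object@savr
      if (!(s["min"] <= s["best"] && s["best"] <= s["max"]))
        return("SA/V variants must satisfy min <= best <= max")
    }
    TRUE
  }
)

#' Energetic constants for the bioenergetics layer
#'
#' Literature constants for northern elephant seals: water-free fractions and
#' energy densities of lean and lipid tissue, baseline field metabolic rate,
#' blood volume as a fraction of body mass, and the per-degree febrile
#' increase in metabolic rate.
#'
#' @slot leanDryFraction unitless (0.27): water-free proportion of lean tissue.
#' @slot leanEnergyDensity MJ/kg dry lean tissue (17.99).
#' @slot lipidDryFraction unitless (0.90).
#' @slot lipidEnergyDensity MJ/kg dry lipid (39.33).
#' @slot fmrBaseline kJ/kg/day (90.1), post-breeding field metabolic rate.
#' @slot bloodFraction blood volume as fraction of body mass (0.202).
#' @slot feverIncreasePerDegC unitless per degree C, the low/high endotherm
#'   range `c(0.10, 0.125)`.
#' @export
setClass("EnergyConstants",
  representation(leanDryFraction = "numeric", leanEnergyDensity = "numeric",
                 lipidDryFraction = "numeric", lipidEnergyDensity = "numeric",
                 fmrBaseline = "numeric", bloodFraction = "numeric",
                 feverIncreasePerDegC = "numeric"),
  prototype(leanDryFraction = 0.27, leanEnergyDensity = 17.99,
            lipidDryFraction = 0.90, lipidEnergyDensity = 39.33,
            fmrBaseline = 90.1, bloodFraction = 0.202,
            feverIncreasePerDegC = c(0.10, 0.125)),
  validity = function(object) {
    vals <- c(object@leanDryFraction, object@leanEnergyDensity,
              object@lipidDryFraction, object@lipidEnergyDensity,
              object@fmrBaseline, object@bloodFraction,
              object@feverIncreasePerDegC)
    if (any(vals <= 0)) return("all constants must be positive")
    if (object@leanDryFraction > 1 || object@lipidDryFraction > 1 ||
        object@bloodFraction > 1) return("fractions must be <= 1")
    TRUE
  }
)

#' @rdname EnergyConstants-class
#' @param ... named slot overrides, e.g. `fmrBaseline = 95`.
#' @return An [EnergyConstants-class] object.
#' @export
energyConstants <- function(...) new("EnergyConstants", ...)

#' Trip energy budget
#'
#' Tissue losses and their energy equivalents for a foraging trip, plus any
#' named scenario costs (e.g. fever, no-foraging FMR).
#'
#' @slot leanLossKg,lipidLossKg kg of tissue lost (negative = gained).
#' @slot leanMJ,lipidMJ,totalMJ MJ.
#' @slot leanSharePct percent of total energy derived from lean tissue.
#' @slot scenarios named numeric, MJ per scenario.
#' @export
setClass("EnergyBudget",
  representation(leanLossKg = "numeric", lipidLossKg = "numeric",
                 leanMJ = "numeric", lipidMJ = "numeric", totalMJ = "numeric",
                 leanSharePct = "numeric", scenarios = "numeric"),
  validity = function(object) {
    if (abs(object@totalMJ - (object@leanMJ + object@lipidMJ)) > 1e-6)
      return("totalMJ must equal leanMJ + lipidMJ")
    TRUE
  }
)

#' Synthetic trip configuration
#'
#' All knobs of the seeded synthetic-trip generator. Defaults emulate a
#' healthy adult female northern elephant seal on a post-breeding foraging
#' trip: 20-40 min dives to 400-600 m (deeper by day), ~2 min post-dive
#' intervals, 1000-1500 prey-capture attempts per day. Setting
#' `illnessWindow` switches on the sick regime: uniformly long (3-30 min)
#' PDIs inside the window, optional rare highly extended (30-200 min) PDIs
#' after it, and suppressed foraging.
#'
#' @slot seed integer RNG seed. @slot tripDays trip length, days.
#' @slot sampleInterval TDR sampling interval, s (default 8).
#' @slot diveDurationMean,diveDurationSd minutes.
#' @slot diveDurationTrend minutes per day drift of the mean duration
#'   (negative = declining through the trip; default 0).
#' @slot diveDepthDayMean,diveDepthNightMean,diveDepthSd metres.
#' @slot pdiMean,pdiSd minutes (healthy regime, truncated log-normal, 0.5 min
#'   floor).
#' @slot descentRate,ascentRate m/s.
#' @slot wiggleRate wiggles per bottom-minute.
#' @slot illnessWindow numeric(0) for healthy, else `c(startDay, endDay)`;
#'   active on trip days `startDay <= d < endDay` (day 0 = first 24 h).
#' @slot illnessPdiRange minutes `c(lo, hi)` for in-window PDIs.
#' @slot lateExtendedPdiProb per-dive probability of an extended PDI after
#'   the window. @slot lateExtendedPdiRange minutes `c(lo, hi)`.
#' @slot eventsPerDayHealthy,eventsPerDaySick jaw-motion events per day.
#' @slot sensorOffsetStart,sensorOffsetEnd metres; linear pressure-sensor
#'   drift over the record. @slot noiseSd metres of Gaussian sensor noise.
#' @slot colonyLatLon `c(lat, lon)` degrees of the colony.
#' @slot dailyDisplacement km travelled per day.
#' @slot tripStart epoch seconds UTC of trip start.
#' @export
setClass("SimConfig",
  representation(seed = "numeric", tripDays = "numeric",
                 sampleInterval = "numeric",
                 diveDurationMean = "numeric", diveDurationSd = "numeric",
                 diveDurationTrend = "numeric",
                 diveDepthDayMean = "numeric", diveDepthNightMean = "numeric",
                 diveDepthSd = "numeric",
                 pdiMean = "numeric", pdiSd = "numeric",
                 descentRate = "numeric", ascentRate = "numeric",
                 wiggleRate = "numeric",
                 illnessWindow = "numeric", illnessPdiRange = "numeric",
                 lateExtendedPdiProb = "numeric",
                 lateExtendedPdiRange = "numeric",
                 eventsPerDayHealthy = "numeric", eventsPerDaySick = "numeric",
                 sensorOffsetStart = "numeric", sensorOffsetEnd = "numeric",
                 noiseSd = "numeric", colonyLatLon = "numeric",
                 dailyDisplacement = "numeric", tripStart = "numeric"),
  prototype(seed = 1, tripDays = 10, sampleInterval = 8,
            diveDurationMean = 22, diveDurationSd = 4, diveDurationTrend = 0,
            diveDepthDayMean = 570, diveDepthNightMean = 490, diveDepthSd = 80,
            pdiMean = 2, pdiSd = 0.8, descentRate = 1.3, ascentRate = 1.2,
            wiggleRate = 0.5, illnessWindow = numeric(0),
            illnessPdiRange = c(3, 30), lateExtendedPdiProb = 0,
            lateExtendedPdiRange = c(30, 200),
            eventsPerDayHealthy = 1250, eventsPerDaySick = 300,
            sensorOffsetStart = 0, sensorOffsetEnd = 0, noiseSd = 0.2,
            colonyLatLon = c(37.108, -122.336), dailyDisplacement = 70,
            tripStart = 1486252800),  # 2017-02-05 00:00:00 UTC
  validity = function(object) {
    msg <- character(0)
    nonneg <- c(diveDurationSd = object@diveDurationSd,
                diveDepthSd = object@diveDepthSd, pdiSd = object@pdiSd,
                wiggleRate = object@wiggleRate, noiseSd = object@noiseSd,
                lateExtendedPdiProb = object@lateExtendedPdiProb,
                eventsPerDayHealthy = object@eventsPerDayHealthy,
                eventsPerDaySick = object@eventsPerDaySick)
    if (any(nonneg < 0))
      msg <- c(msg, paste("must be >= 0:",
                          paste(names(nonneg)[nonneg < 0], collapse = ", ")))
    if (object@sampleInterval <= 0) msg <- c(msg, "sampleInterval must be > 0")
    if (object@tripDays <= 0) msg <- c(msg, "tripDays must be > 0")
    if (object@descentRate <= 0 || object@ascentRate <= 0)
      msg <- c(msg, "descent/ascent rates must be > 0")
    iw <- object@illnessWindow
    if (length(iw) && (length(iw) != 2 || iw[1] < 0 || iw[2] < iw[1] ||
                       iw[2] > object@tripDays))
      msg <- c(msg, "illnessWindow must be c(start, end) within [0, tripDays]")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname SimConfig-class
#' @param ... named slot overrides (see slot list above), e.g.
#'   `simConfig(seed = 7, tripDays = 80, illnessWindow = c(8, 20))`.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(...) new("SimConfig", ...)

#' A complete simulated foraging trip
#'
#' Bundles the corrupted depth record, the generator's ground-truth dive
#' table, the hourly location track, jaw-motion event timestamps and the
#' paired departure/arrival morphometry.
#'
#' @slot depthRecord [DepthRecord-class] with sensor drift and noise applied.
#' @slot truthDives [DiveTable-class], the uncorrupted ground truth.
#' @slot track [Track-class] hourly positions.
#' @slot jawEvents numeric epoch seconds of prey-capture attempts.
#' @slot morphometryPair list of two [MorphometryRecord-class] objects,
#'   `departure` and `arrival`.
#' @slot config the generating [SimConfig-class].
#' @export
setClass("SimulatedTrip",
  representation(depthRecord = "DepthRecord", truthDives = "DiveTable",
                 track = "Track", jawEvents = "numeric",
                 morphometryPair = "list", config = "SimConfig"))

#' Trip-level behavioural and energetic summary
#'
#' @slot metrics named list of trip metrics (mass/energy gains, duration,
#'   distances, dive counts, extended-PDI count, and grand means +/- SD of
#'   the diving statistics split by day/night).
#' @export
setClass("TripSummary", representation(metrics = "list"))
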