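# Aggregation of jaw-motion (prey-capture-attempt) event timestamps into
# daily counts, event depths and percent time foraging.

#' Jaw-motion events per trip day
#'
#' Bins event timestamps into 24-hour windows anchored at the trip start
#' (not civil midnight), so day indices match "day of trip" elsewhere in the
#' pipeline. Every day is returned, including zero-count days; days above
#' the high-effort threshold (default 1500/day) are flagged.
#'
#' @param events numeric/POSIXct event timestamps.
#' @param tripStart trip start time (POSIXct, ISO string or epoch seconds).
#' @param tripDays number of days to report; default covers the last event.
#' @param threshold events/day above which a day is flagged (default 1500).
#' @return data.frame with `trip_day` (0-based), `count`,
#'   `exceeds_threshold`.
#' @export
eventsPerDay <- function(events, tripStart, tripDays = NULL,
                         threshold = 1500) {
  t0 <- .asEpoch(tripStart)
  ev <- .asEpoch(events)
  if (length(ev) && any(ev < t0)) stop("events before trip start")
  day <- floor((ev - t0) / 86400)
  if (is.null(tripDays))
    tripDays <- if (length(ev)) max(day) + 1L else 1L
  counts <- tabulate(day + 1L, nbins = tripDays)
  data.frame(trip_day = 0:(tripDays - 1), count = counts,
             exceeds_threshold = counts > threshold)
}

#' Depths of jaw-motion events
#'
#' Depth at each event by linear interpolation of the depth series, plus
#' per-trip-day mean depths and a binned density of event depths
#' (normalised to integrate to 1). Events outside the record span are
#' excluded with a message.
#'
#' @param events event timestamps.
#' @param record a [DepthRecord-class] (use the corrected record).
#' @param binWidth density bin width, m (default 10).
#' @param tripStart anchor for day bins; defaults to the record start.
#' @return List with `depths` (per retained event), `excluded` (count),
#'   `daily_mean` (data.frame `trip_day`, `mean_depth`, `n`), and `density`
#'   (data.frame `mid`, `density`).
#' @export
eventDepths <- function(events, record, binWidth = 10, tripStart = NULL) {
  stopifnot(is(record, "DepthRecord"))
  ev <- .asEpoch(events)
  t0 <- if (is.null(tripStart)) record@time[1] else .asEpoch(tripStart)
  inside <- ev >= record@time[1] & ev <= record@time[length(record@time)]
  if (any(!inside))
    message(sum(!inside), " event(s) outside the depth record excluded")
  ev <- ev[inside]
  if (!length(ev))
    return(list(depths = numeric(0), excluded = sum(!inside),
                daily_mean = data.frame(trip_day = integer(0),
                                        mean_depth = numeric(0),
                                        n = integer(0)),
                density = data.frame(mid = numeric(0), density = numeric(0))))
  dep <- stats::approx(record@time, record@depth, xout = ev)$y
  day <- floor((ev - t0) / 86400)
  agg <- stats::aggregate(dep, list(trip_day = day),
                          function(v) c(mean = mean(v), n = length(v)))
  daily <- data.frame(trip_day = agg$trip_day,
                      mean_depth = agg$x[, "mean"], n = agg$x[, "n"])
  breaks <- seq(0, max(dep) + binWidth, by = binWidth)
  h <- graphics::hist(dep, breaks = breaks, plot = FALSE)
  list(depths = dep, excluded = sum(!inside), daily_mean = daily,
       density = data.frame(mid = h$mids, density = h$density))
}

#' Percent of at-sea time spent foraging
#'
#' A dive counts as foraging when it contains at least `k` jaw-motion
#' events (an operational surrogate for accelerometer-based dive
#' classification). Percent time foraging is 100 x (summed duration of
#' foraging dives) / (total at-sea time, i.e. dive durations plus post-dive
#' intervals), reported trip-wide and per trip day.
#'
#' @param events event timestamps.
#' @param dives a [DiveTable-class].
#' @param k minimum events for a dive to count as foraging (default 1).
#' @param tripStart anchor for day bins; defaults to the first dive start.
#' @return List with `trip_pct`, `daily` (data.frame `trip_day`, `pct`) and
#'   `foraging_dive` (logical per dive).
#' @export
percentTimeForaging <- function(events, dives, k = 1, tripStart = NULL) {
  stopifnot(is(dives, "DiveTable"))
  d <- diveData(dives)
  if (!nrow(d))
    return(list(trip_pct = 0,
                daily = data.frame(trip_day = integer(0), pct = numeric(0)),
                foraging_dive = logical(0)))
  ev <- sort(.asEpoch(events))
  nEv <- findInterval(d$end_time, ev) - findInterval(d$start_time, ev)
  foraging <- nEv >= k
  atSea <- d$duration_min + ifelse(is.na(d$pdi_min), 0, d$pdi_min)
  t0 <- if (is.null(tripStart)) d$start_time[1] else .asEpoch(tripStart)
  day <- floor((d$start_time - t0) / 86400)
  dailyPct <- vapply(sort(unique(day)), function(dd) {
    i <- day == dd
    100 * sum(d$duration_min[i & foraging]) / sum(atSea[i])
  }, numeric(1))
  list(trip_pct = 100 * sum(d$duration_min[foraging]) / sum(atSea),
       daily = data.frame(trip_day = sort(unique(day)), pct = dailyPct),
       foraging_dive = foraging)
}
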