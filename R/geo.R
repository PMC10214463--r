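# Track geometry: interpolation, great-circle distances, solar elevation and
# day/night classification of dives.

#' Interpolate a track to a regular interval
#'
#' Linear interpolation of latitude and longitude onto a regular time grid
#' (default hourly). Endpoints are preserved. Linear lat/lon interpolation
#' (rather than great-circle) is adequate at hourly spacing for a ~70 km/day
#' animal; errors are metres.
#'
#' @param track a [Track-class] with at least two fixes.
#' @param interval grid spacing in hours (default 1).
#' @return A [Track-class] on the regular grid (plus the final fix if it does
#'   not fall on the grid).
#' @export
interpolateTrack <- function(track, interval = 1) {
  stopifnot(is(track, "Track"))
  if (length(track@time) < 2) stop("need at least two fixes")
  if (anyDuplicated(track@time)) stop("duplicate timestamps in track")
  tt <- seq(track@time[1], track@time[length(track@time)],
            by = interval * 3600)
  if (tt[length(tt)] < track@time[length(track@time)])
    tt <- c(tt, track@time[length(track@time)])
  Track(tt,
        stats::approx(track@time, track@lat, xout = tt)$y,
        stats::approx(track@time, track@lon, xout = tt)$y)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km. Vectorised over
#' point pairs.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' greatCircleKm(0, 0, 0, 1)   # ~111.19 km
#' @export
greatCircleKm <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Total and maximum-from-colony trip distances
#'
#' @param track an (interpolated) [Track-class].
#' @param colony `c(lat, lon)` of the colony, decimal degrees.
#' @return A list with `total_km` (sum of consecutive great-circle segments)
#'   and `max_from_colony_km`.
#' @export
tripDistances <- function(track, colony) {
  stopifnot(is(track, "Track"), length(colony) == 2)
  n <- length(track@time)
  total <- if (n < 2) 0 else
    sum(greatCircleKm(track@lat[-n], track@lon[-n],
                      track@lat[-1], track@lon[-1]))
  maxd <- max(greatCircleKm(track@lat, track@lon, colony[1], colony[2]))
  list(total_km = total, max_from_colony_km = maxd)
}

#' Solar elevation angle
#'
#' Geometric solar elevation (degrees above the horizon, no atmospheric
#' refraction) from the NOAA solar position calculations: solar declination
#' and the equation of time from the Julian-century series used by the NOAA
#' solar calculator, then the hour angle and elevation from the spherical
#' triangle. Accuracy is better than 0.1 degree over 1950-2100, ample for
#' day/night classification.
#'
#' @param time POSIXct (UTC), ISO-8601 strings, or epoch seconds. Vectorised;
#'   recycled against `lat`/`lon`.
#' @param lat,lon decimal degrees (east longitude positive).
#' @return Solar elevation in degrees.
#' @examples
#' solarElevation(as.POSIXct("2017-03-20 12:07:00", tz = "UTC"), 0, 0)  # ~ 90
#' @export
solarElevation <- function(time, lat, lon) {
  t <- .asEpoch(time)
  if (any(t < -631152000 | t > 4133980800))   # 1950-01-01 .. 2101-01-01
    stop("time must be within years 1950-2100")
  deg <- pi / 180
  jc <- (t / 86400 + 2440587.5 - 2451545) / 36525   # Julian centuries J2000
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqcent <- sin(gmas * deg) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * deg) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * deg) * 0.000289
  truelong <- gmls + eqcent
  applong <- truelong - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * deg)
  obliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliqc <- obliq + 0.00256 * cos((125.04 - 1934.136 * jc) * deg)
  decl <- asin(sin(obliqc * deg) * sin(applong * deg))
  vy <- tan(obliqc / 2 * deg)^2
  eqtime <- 4 / deg * (vy * sin(2 * gmls * deg) - 2 * ecc * sin(gmas * deg) +
    4 * ecc * vy * sin(gmas * deg) * cos(2 * gmls * deg) -
    0.5 * vy^2 * sin(4 * gmls * deg) - 1.25 * ecc^2 * sin(2 * gmas * deg))

  mins <- (t %% 86400) / 60                        # minutes past 0h UTC
  tst <- (mins + eqtime + 4 * lon) %% 1440         # true solar time, minutes
  ha <- (tst / 4 - 180) * deg                      # hour angle, rad
  latr <- lat * deg
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) / deg
}

#' Assign locations and day/night flags to dives
#'
#' Each dive gets a latitude/longitude by linear time-interpolation of the
#' track at the dive's reference timestamp, and is flagged day if the solar
#' elevation there is strictly greater than 0 degrees (ties at exactly 0 are
#' classified night). Dives outside the track's time span are left unlocated
#' (`lat`/`lon`/`is_day` = `NA`) and are excluded from day/night splits.
#'
#' @param dives a [DiveTable-class].
#' @param track a [Track-class] spanning (most of) the dive record.
#' @param at which timestamp represents the dive: `"start"` (default),
#'   `"mid"` or `"end"`.
#' @return The [DiveTable-class] with `lat`, `lon`, `is_day` filled in.
#' @export
classifyDayNight <- function(dives, track, at = c("start", "mid", "end")) {
  stopifnot(is(dives, "DiveTable"), is(track, "Track"))
  at <- match.arg(at)
  d <- diveData(dives)
  if (!nrow(d)) return(dives)
  tref <- switch(at, start = d$start_time,
                 mid = (d$start_time + d$end_time) / 2,
                 end = d$end_time)
  inside <- tref >= track@time[1] & tref <= track@time[length(track@time)]
  d$lat <- d$lon <- NA_real_
  d$is_day <- NA
  if (any(inside)) {
    d$lat[inside] <- stats::approx(track@time, track@lat, xout = tref[inside])$y
    d$lon[inside] <- stats::approx(track@time, track@lon, xout = tref[inside])$y
    elev <- solarElevation(tref[inside], d$lat[inside], d$lon[inside])
    d$is_day[inside] <- elev > 0
  }
  DiveTable(d)
}
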