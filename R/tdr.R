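# TDR processing: zero-offset correction, subsampling, dive detection and
# per-dive statistics.

#' Zero-offset correct a depth record
#'
#' Pressure sensors drift, so raw "surface" readings wander away from 0 m.
#' The correction estimates the surface baseline as a rolling low percentile
#' of depth (surface samples are the shallow tail of any window that contains
#' both dives and surface intervals), interpolates the window-centre estimates
#' linearly across the record, subtracts the baseline, and clips residual
#' negative depths to zero.
#'
#' @param record a [DepthRecord-class].
#' @param window rolling window length in minutes (default 30). Windows
#'   overlap by half their length. Must cover at least 10 samples.
#' @param percentile lower percentile taken as the surface baseline within
#'   each window (default 0.02); a low percentile rather than the minimum so
#'   that negative noise spikes do not drag the baseline down.
#' @return A list with `record` (the corrected [DepthRecord-class]) and
#'   `baseline` (the per-sample estimated offset, m).
#' @examples
#' rec <- DepthRecord(seq(0, 7200 - 8, by = 8), rep(3, 900))  # constant 3 m offset
#' out <- zeroOffsetCorrect(rec, window = 30)
#' max(abs(depths(out$record)))  # ~0
#' @export
zeroOffsetCorrect <- function(record, window = 30, percentile = 0.02) {
  stopifnot(is(record, "DepthRecord"))
  dt <- record@interval
  wsec <- window * 60
  if (wsec < 10 * dt)
    stop("window must cover at least 10 samples")
  n <- length(record@depth)
  span <- record@time[n] - record@time[1]
  if (span < wsec) stop("record too short for the requested window")

  wlen <- max(10L, as.integer(round(wsec / dt)))        # samples per window
  step <- max(1L, wlen %/% 2L)                          # half-overlapping
  starts <- seq(1L, max(1L, n - wlen + 1L), by = step)
  centres <- starts + (wlen - 1L) / 2
  base <- vapply(starts, function(s) {
    stats::quantile(record@depth[s:min(n, s + wlen - 1L)], percentile,
                    names = FALSE, type = 7)
  }, numeric(1))
  # a window lying entirely within a dive longer than the window sees no
  # surface; a short rolling minimum lets such windows inherit the surface
  # estimate from their neighbours
  nb <- length(base)
  base <- vapply(seq_len(nb), function(i)
    min(base[max(1L, i - 2L):min(nb, i + 2L)]), numeric(1))
  baseline <- stats::approx(centres, base, xout = seq_len(n), rule = 2)$y
  corrected <- pmax(record@depth - baseline, 0)
  list(record = new("DepthRecord", time = record@time, depth = corrected,
                    interval = dt),
       baseline = baseline)
}

#' Subsample a depth record to a coarser interval
#'
#' Decimates by keeping every k-th sample (the first sample is retained);
#' used to put records from tags with different native rates on a common
#' 8-second grid before comparing dive statistics.
#'
#' @param record a [DepthRecord-class].
#' @param targetInterval target sampling interval in seconds; must be an
#'   integer multiple of the native interval.
#' @return A [DepthRecord-class] at the target interval.
#' @export
subsampleRecord <- function(record, targetInterval = 8) {
  stopifnot(is(record, "DepthRecord"))
  k <- targetInterval / record@interval
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("targetInterval must be an integer multiple of the native interval")
  k <- as.integer(round(k))
  if (k == 1L) return(record)
  idx <- seq(1L, length(record@depth), by = k)
  new("DepthRecord", time = record@time[idx], depth = record@depth[idx],
      interval = record@interval * k)
}

#' Detect dives in a zero-offset-corrected record
#'
#' A dive is a maximal contiguous run of samples deeper than
#' `surfaceThreshold` whose maximum depth reaches `minDepth` and whose
#' duration reaches `minDuration`. Start/end are taken one sample outside the
#' run (the samples bracketing the surface crossings) so boundary times match
#' the true surfacing moments to within one sample. The post-dive interval
#' (PDI) is the gap from each dive's end to the next dive's start.
#'
#' @param record a corrected [DepthRecord-class].
#' @param minDepth minimum maximum-depth for a run to count as a dive, m
#'   (default 15, a field-standard threshold for deep-diving phocids).
#' @param minDuration minimum dive duration, s (default 32, i.e. 4 samples at
#'   8 s).
#' @param surfaceThreshold depth above which the animal is considered
#'   submerged, m (default 2).
#' @param bottomFraction,wiggleMin passed to [diveStats()].
#' @return A [DiveTable-class] with per-dive statistics filled in.
#' @export
detectDives <- function(record, minDepth = 15, minDuration = 32,
                        surfaceThreshold = 2, bottomFraction = 0.8,
                        wiggleMin = 5) {
  stopifnot(is(record, "DepthRecord"))
  n <- length(record@depth)
  wet <- record@depth > surfaceThreshold
  if (!any(wet)) return(DiveTable())
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  dt <- record@interval

  rows <- list()
  for (j in keep) {
    s <- starts[j]; e <- ends[j]
    # bracket the surface crossings
    s0 <- max(1L, s - 1L); e0 <- min(n, e + 1L)
    if ((e0 - s0) * dt < minDuration) next
    if (max(record@depth[s:e]) < minDepth) next
    rows[[length(rows) + 1L]] <- c(s0, e0)
  }
  if (!length(rows)) return(DiveTable())
  idx <- do.call(rbind, rows)

  stats <- lapply(seq_len(nrow(idx)), function(i)
    diveStats(record, start = idx[i, 1], end = idx[i, 2],
              bottomFraction = bottomFraction, wiggleMin = wiggleMin))
  d <- do.call(rbind, stats)
  # PDI: gap from dive end to next dive start, minutes; NA for the last dive
  d$pdi_min <- c((d$start_time[-1] - d$end_time[-nrow(d)]) / 60, NA_real_)
  DiveTable(d)
}

#' Per-dive statistics
#'
#' Computes the standard dive statistics for one dive of a record: maximum
#' depth, duration, bottom time (the span of samples at or below
#' `bottomFraction` of maximum depth), descent/ascent rates (surface to
#' first/last bottom-phase sample), and the wiggle count (local depth maxima
#' within the bottom phase with prominence of at least `wiggleMin` metres, a
#' proxy for prey pursuit).
#'
#' @param record a [DepthRecord-class].
#' @param start,end sample indices bracketing the dive.
#' @param bottomFraction bottom phase is depth >= this fraction of maximum
#'   depth (default 0.8).
#' @param wiggleMin minimum prominence (m) for a local maximum to count as a
#'   wiggle (default 5).
#' @return A one-row data.frame of dive statistics (the row format of
#'   [diveData()]). Degenerate dives of fewer than three samples get zero
#'   statistics and `flag_degenerate = TRUE` with a warning.
#' @export
diveStats <- function(record, start, end, bottomFraction = 0.8,
                      wiggleMin = 5) {
  stopifnot(is(record, "DepthRecord"),
            start >= 1, end <= length(record@depth), start < end)
  dt <- record@interval
  dep <- record@depth[start:end]
  t0 <- record@time[start]; t1 <- record@time[end]
  out <- data.frame(start_idx = as.integer(start), end_idx = as.integer(end),
                    start_time = t0, end_time = t1,
                    max_depth = max(dep), duration_min = (t1 - t0) / 60,
                    bottom_time_min = 0, n_wiggles = 0L,
                    descent_rate = 0, ascent_rate = 0,
                    pdi_min = NA_real_, is_day = NA, lat = NA_real_,
                    lon = NA_real_, flag_degenerate = FALSE)
  if (length(dep) < 3) {
    warning("degenerate dive (", length(dep), " samples): statistics set to 0")
    out$flag_degenerate <- TRUE
    return(out)
  }
  maxd <- max(dep)
  bot <- which(dep >= bottomFraction * maxd)
  b1 <- bot[1]; b2 <- bot[length(bot)]
  out$bottom_time_min <- (b2 - b1) * dt / 60
  surf0 <- dep[1]; surf1 <- dep[length(dep)]
  if (b1 > 1) out$descent_rate <- (dep[b1] - surf0) / ((b1 - 1) * dt)
  if (b2 < length(dep))
    out$ascent_rate <- (dep[b2] - surf1) / ((length(dep) - b2) * dt)
  out$n_wiggles <- .countWiggles(dep[b1:b2], wiggleMin)
  out
}

# Local maxima with topographic prominence >= minProm. Prominence of a peak is
# its height above the higher of the two lowest points reached before meeting
# taller terrain on each side (record boundaries count as taller terrain for
# the purpose of the descent, i.e. the walk stops there).
.countWiggles <- function(x, minProm) {
  n <- length(x)
  if (n < 3) return(0L)
  pk <- which(diff(sign(diff(x))) < 0) + 1L   # strict local maxima
  if (!length(pk)) return(0L)
  count <- 0L
  for (p in pk) {
    h <- x[p]
    lmin <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) { if (x[i] < lmin) lmin <- x[i]; i <- i - 1L }
    rmin <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) { if (x[i] < rmin) rmin <- x[i]; i <- i + 1L }
    if (h - max(lmin, rmin) >= minProm) count <- count + 1L
  }
  count
}

#' Extended surface intervals
#'
#' Returns the post-dive intervals strictly longer than a threshold, with
#' their timestamps and day/night flags. Repeated long surface intervals
#' (minutes to hours instead of the usual ~2 min) are a behavioural anomaly
#' associated with illness.
#'
#' @param dives a [DiveTable-class].
#' @param threshold minutes (default 4, the trip-report convention).
#' @return A list with `count` and `intervals` (data.frame of `end_time`
#'   POSIXct, `pdi_min`, `is_day`).
#' @export
extendedSurfaceIntervals <- function(dives, threshold = 4) {
  stopifnot(is(dives, "DiveTable"))
  d <- diveData(dives)
  if (!nrow(d)) stop("dive table is empty")
  sel <- which(!is.na(d$pdi_min) & d$pdi_min > threshold)
  list(count = length(sel),
       intervals = data.frame(end_time = .asUTC(d$end_time[sel]),
                              pdi_min = d$pdi_min[sel],
                              is_day = d$is_day[sel]))
}
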