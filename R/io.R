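# Plain-text CSV readers and writers. All timestamps are ISO-8601 UTC
# ("YYYY-MM-DDTHH:MM:SSZ").

.fmtTime <- function(t) format(.asUTC(t), .isoFormat)

#' Read and write depth CSV (`time,depth_m`)
#' @param path CSV file path.
#' @return [readDepthCSV()]: a [DepthRecord-class].
#' @export
readDepthCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "depth_m") %in% names(d)))
    stop("depth CSV must have columns time, depth_m")
  DepthRecord(d$time, d$depth_m)
}

#' @rdname readDepthCSV
#' @param record a [DepthRecord-class].
#' @export
writeDepthCSV <- function(record, path) {
  utils::write.csv(data.frame(time = .fmtTime(record@time),
                              depth_m = record@depth),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write track CSV (`time,lat,lon`)
#' @param path CSV file path.
#' @return [readTrackCSV()]: a [Track-class].
#' @export
readTrackCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "lat", "lon") %in% names(d)))
    stop("track CSV must have columns time, lat, lon")
  Track(d$time, d$lat, d$lon)
}

#' @rdname readTrackCSV
#' @param track a [Track-class].
#' @export
writeTrackCSV <- function(track, path) {
  utils::write.csv(data.frame(time = .fmtTime(track@time),
                              lat = track@lat, lon = track@lon),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write event-timestamp CSV (`time`)
#' @param path CSV file path.
#' @return [readEventsCSV()]: numeric epoch seconds.
#' @export
readEventsCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(d)) stop("events CSV must have column time")
  .asEpoch(d$time)
}

#' @rdname readEventsCSV
#' @param events event timestamps.
#' @export
writeEventsCSV <- function(events, path) {
  utils::write.csv(data.frame(time = .fmtTime(.asEpoch(events))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dive-table CSV
#'
#' One row per dive with the fixed column set of [diveData()]; times
#' ISO-8601 UTC.
#' @param path CSV file path.
#' @return [readDiveTableCSV()]: a [DiveTable-class].
#' @export
readDiveTableCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$start_time <- .asEpoch(d$start_time)
  d$end_time <- .asEpoch(d$end_time)
  DiveTable(d)
}

#' @rdname readDiveTableCSV
#' @param dives a [DiveTable-class].
#' @export
writeDiveTableCSV <- function(dives, path) {
  d <- diveData(dives)
  d$start_time <- .fmtTime(d$start_time)
  d$end_time <- .fmtTime(d$end_time)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write morphometry CSV
#'
#' Wide format, one row per sedation: `stage`, `mass_kg`,
#' `standard_length_cm`, `fasting_days`, `station_pos_1..6`, `girth_1..6`,
#' `blubber_dorsal_1..6`, `blubber_lateral_1..6` (girths/blubber in cm).
#' @param path CSV file path.
#' @return [readMorphometryCSV()]: a named list of
#'   [MorphometryRecord-class] objects keyed by stage.
#' @export
readMorphometryCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(d)), function(i) {
    MorphometryRecord(
      mass = d$mass_kg[i], standardLength = d$standard_length_cm[i],
      girths = as.numeric(d[i, paste0("girth_", 1:6)]),
      blubberDorsal = as.numeric(d[i, paste0("blubber_dorsal_", 1:6)]),
      blubberLateral = as.numeric(d[i, paste0("blubber_lateral_", 1:6)]),
      stationPositions = as.numeric(d[i, paste0("station_pos_", 1:6)]),
      fastingDays = d$fasting_days[i], stage = d$stage[i])
  })
  stats::setNames(recs, d$stage)
}

#' @rdname readMorphometryCSV
#' @param records list of [MorphometryRecord-class] objects.
#' @export
writeMorphometryCSV <- function(records, path) {
  rows <- lapply(records, function(m) {
    row <- data.frame(stage = m@stage, mass_kg = m@mass,
                      standard_length_cm = m@standardLength,
                      fasting_days = m@fastingDays)
    for (j in 1:6) {
      row[[paste0("station_pos_", j)]] <- m@stationPositions[j]
      row[[paste0("girth_", j)]] <- m@girths[j]
      row[[paste0("blubber_dorsal_", j)]] <- m@blubberDorsal[j]
      row[[paste0("blubber_lateral_", j)]] <- m@blubberLateral[j]
    }
    row
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write all components of a simulated trip to a directory
#'
#' Writes `depth.csv`, `track.csv`, `events.csv`, `morphometry.csv` and
#' `truth_dives.csv`.
#'
#' @param trip a [SimulatedTrip-class].
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
writeTripCSV <- function(trip, dir) {
  stopifnot(is(trip, "SimulatedTrip"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeDepthCSV(trip@depthRecord, file.path(dir, "depth.csv"))
  writeTrackCSV(trip@track, file.path(dir, "track.csv"))
  writeEventsCSV(trip@jawEvents, file.path(dir, "events.csv"))
  writeMorphometryCSV(trip@morphometryPair, file.path(dir, "morphometry.csv"))
  writeDiveTableCSV(trip@truthDives, file.path(dir, "truth_dives.csv"))
  invisible(dir)
}
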