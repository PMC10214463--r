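# Accessors and show methods for the core classes.

#' @rdname DepthRecord-class
#' @export
setMethod("depths", "DepthRecord", function(x) x@depth)

#' @rdname DepthRecord-class
#' @export
setMethod("recordTime", "DepthRecord", function(x) .asUTC(x@time))

#' @rdname DepthRecord-class
#' @export
setMethod("sampleInterval", "DepthRecord", function(x) x@interval)

#' @rdname DepthRecord-class
#' @export
setMethod("length", "DepthRecord", function(x) length(x@depth))

setMethod("show", "DepthRecord", function(object) {
  n <- length(object@depth)
  cat("DepthRecord:", n, "samples @", object@interval, "s\n")
  if (n) {
    cat("  span :", format(.asUTC(object@time[1]), .isoFormat), "to",
        format(.asUTC(object@time[n]), .isoFormat),
        sprintf("(%.2f days)\n", (object@time[n] - object@time[1]) / 86400))
    cat(sprintf("  depth: max %.1f m, mean %.1f m\n",
                max(object@depth), mean(object@depth)))
  }
})

#' @rdname DiveTable-class
#' @export
setMethod("diveData", "DiveTable", function(x) x@dives)

#' @rdname DiveTable-class
#' @export
setMethod("nDives", "DiveTable", function(x) nrow(x@dives))

#' @rdname DiveTable-class
#' @export
setMethod("length", "DiveTable", function(x) nrow(x@dives))

#' @rdname DiveTable-class
#' @param row.names,optional,... passed through (S3 convention).
#' @export
as.data.frame.DiveTable <- function(x, row.names = NULL, optional = FALSE, ...)
  x@dives

setMethod("show", "DiveTable", function(object) {
  d <- object@dives
  cat("DiveTable:", nrow(d), "dives\n")
  if (nrow(d)) {
    cat(sprintf("  max depth: %.1f +/- %.1f m | duration: %.1f +/- %.1f min | PDI: %.1f min (median)\n",
                mean(d$max_depth), stats::sd(d$max_depth),
                mean(d$duration_min), stats::sd(d$duration_min),
                stats::median(d$pdi_min, na.rm = TRUE)))
    if (!all(is.na(d$is_day)))
      cat("  day/night:", sum(d$is_day, na.rm = TRUE), "day,",
          sum(!d$is_day, na.rm = TRUE), "night\n")
  }
})

#' @rdname Track-class
#' @export
setMethod("trackData", "Track", function(x)
  data.frame(time = .asUTC(x@time), lat = x@lat, lon = x@lon))

#' @rdname Track-class
#' @export
setMethod("length", "Track", function(x) length(x@time))

setMethod("show", "Track", function(object) {
  cat("Track:", length(object@time), "fixes\n")
  if (length(object@time))
    cat(sprintf("  lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
                min(object@lat), max(object@lat),
                min(object@lon), max(object@lon)))
})

setMethod("show", "MorphometryRecord", function(object) {
  cat(sprintf("MorphometryRecord (%s): %.1f kg, SL %.0f cm, %d days fasting\n",
              object@stage, object@mass, object@standardLength,
              as.integer(object@fastingDays)))
  cat("  girths (cm):", paste(sprintf("%.0f", object@girths), collapse = " "), "\n")
  cat(sprintf("  blubber (cm): %.2f dorsal / %.2f lateral (mean)\n",
              mean(object@blubberDorsal), mean(object@blubberLateral)))
})

setMethod("show", "BodyComposition", function(object) {
  cat(sprintf("BodyComposition: %.1f%% adipose (%d kg adipose, %d kg FFM)\n",
              100 * object@adiposeFraction, round(object@adiposeKg),
              round(object@ffmKg)))
  cat(sprintf("  SA %.2f m^2, V %.3f m^3; SA/V min/best/max = %.2f/%.2f/%.2f m^-1\n",
              object@surfaceArea, object@volume,
              object@savr["min"], object@savr["best"], object@savr["max"]))
})

setMethod("show", "EnergyBudget", function(object) {
  cat(sprintf("EnergyBudget: %.1f MJ total (%.1f lean + %.1f lipid; %d%% lean)\n",
              object@totalMJ, object@leanMJ, object@lipidMJ,
              round(object@leanSharePct)))
  if (length(object@scenarios))
    for (nm in names(object@scenarios))
      cat(sprintf("  scenario %-20s %.1f MJ\n", nm, object@scenarios[nm]))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", object@tripDays, "days @",
      object@sampleInterval, "s\n")
  cat(sprintf("  dives %.0f +/- %.0f min to %.0f/%.0f m (day/night); PDI %.1f min\n",
              object@diveDurationMean, object@diveDurationSd,
              object@diveDepthDayMean, object@diveDepthNightMean,
              object@pdiMean))
  if (length(object@illnessWindow))
    cat("  illness window: days", object@illnessWindow[1], "to",
        object@illnessWindow[2], "\n")
})

setMethod("show", "SimulatedTrip", function(object) {
  cat("SimulatedTrip (seed", object@config@seed, ")\n")
  cat("  depth record:", length(object@depthRecord), "samples;",
      nDives(object@truthDives), "truth dives;",
      length(object@jawEvents), "jaw events;",
      length(object@track), "track fixes\n")
})

setMethod("show", "TripSummary", function(object) {
  m <- object@metrics
  cat("TripSummary\n")
  fmt <- function(v) if (is.numeric(v)) sprintf("%.2f", v) else as.character(v)
  for (nm in names(m)) {
    v <- m[[nm]]
    if (length(v) == 1) cat(sprintf("  %-28s %s\n", nm, fmt(v)))
    else if (length(v) == 2 && all(c("mean", "sd") %in% names(v)))
      cat(sprintf("  %-28s %.2f +/- %.2f\n", nm, v["mean"], v["sd"]))
  }
})
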