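# Truncated-cones morphometrics: fasting mass correction, frustum geometry,
# body surface area / volume, composition splits and blubber-shell adipose
# estimation.

#' Fasting mass correction (breeding haul-out)
#'
#' Seals fast on shore, so a mass measured days away from the at-sea endpoint
#' of a trip must be corrected for the intervening fasting loss. The
#' correction is the total mass (kg) lost over `fastingDays` at the
#' mass-dependent daily rate `1.2209 + 0.01329 * mass` kg/day.
#'
#' @param mass measured body mass, kg (> 0).
#' @param fastingDays days fasting between the at-sea endpoint and the
#'   measurement (>= 0).
#' @return Correction in kg.
#' @examples
#' massCorrectionBreed(294, 2)   # 10.256 kg
#' @export
massCorrectionBreed <- function(mass, fastingDays) {
  stopifnot(all(mass > 0))
  if (any(fastingDays < 0)) stop("fastingDays must be non-negative")
  (1.2209 + 0.01329 * mass) * fastingDays
}

#' Truncated-cone (frustum) geometry
#'
#' Closed-form lateral surface area and volume of a circular frustum.
#' `r1 == r2` gives the cylinder limit, `r2 == 0` the full-cone limit.
#'
#' @param r1,r2 end radii, m (>= 0).
#' @param h axial height, m (>= 0).
#' @return A list with `lateral_area` (m^2) and `volume` (m^3); vectorised.
#' @export
coneGeometry <- function(r1, r2, h) {
  if (any(c(r1, r2, h) < 0)) stop("radii and height must be non-negative")
  list(lateral_area = pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2),
       volume = pi * h * (r1^2 + r1 * r2 + r2^2) / 3)
}

# Boundary geometry shared by bodySAV and adiposeFromCones. The coned span
# runs ears -> ankles: 7 frusta bounded by the ear point, the 6 measurement
# stations, and the ankle point. Ear/ankle axial positions are extrapolated
# half a station spacing beyond the outermost stations; their radii are fixed
# fractions of the adjacent station radius (no girth is measured there).
.bodyBoundaries <- function(m, endRadiusFractions) {
  p <- m@stationPositions
  L <- m@standardLength / 100                   # m
  r <- m@girths / (2 * pi) / 100                # m
  if (anyNA(r))
    stop("missing girth at station ", which(is.na(r))[1])
  pe <- max(0.02, p[1] - (p[2] - p[1]) / 2)     # ear boundary
  pa <- min(0.98, p[6] + (p[6] - p[5]) / 2)     # ankle boundary
  bounds <- c(pe, p, pa) * L
  radii <- c(endRadiusFractions[["ear"]] * r[1], r,
             endRadiusFractions[["ankle"]] * r[6])
  list(bounds = bounds, radii = radii, L = L,
       headHeight = pe * L, tailHeight = (1 - pa) * L)
}

#' Body surface area, volume and SA/V by truncated cones
#'
#' The body is represented as seven circular frusta from the ankles to the
#' ears (divided at the six girth stations) with, depending on variant, cones
#' closing the ends: `min` is the frusta alone, `best` adds a circular cone
#' for the head (ears to nose), `max` additionally adds a cone for the tail
#' (ankles to tail tip). SA/V (m^-1) governs heat loss to the water.
#'
#' @param m a [MorphometryRecord-class] with all six girths.
#' @param variant `"best"`, `"min"`, `"max"` or `"all"`.
#' @param endRadiusFractions named numeric `c(ear=, ankle=)`: the unmeasured
#'   ear/ankle boundary radii as fractions of the adjacent station radius.
#' @return A data.frame with columns `variant`, `surface_area` (m^2),
#'   `volume` (m^3) and `sav` (m^-1); one row per requested variant.
#' @export
bodySAV <- function(m, variant = c("best", "min", "max", "all"),
                    endRadiusFractions = c(ear = 0.70, ankle = 0.60)) {
  stopifnot(is(m, "MorphometryRecord"))
  variant <- match.arg(variant)
  g <- .bodyBoundaries(m, endRadiusFractions)
  fr <- coneGeometry(g$radii[-8], g$radii[-1], diff(g$bounds))
  trunkA <- sum(fr$lateral_area); trunkV <- sum(fr$volume)
  head <- coneGeometry(g$radii[1], 0, g$headHeight)
  tail <- coneGeometry(g$radii[8], 0, g$tailHeight)
  res <- data.frame(
    variant = c("min", "best", "max"),
    surface_area = c(trunkA,
                     trunkA + head$lateral_area,
                     trunkA + head$lateral_area + tail$lateral_area),
    volume = c(trunkV,
               trunkV + head$volume,
               trunkV + head$volume + tail$volume))
  res$sav <- res$surface_area / res$volume
  if (variant == "all") res else res[res$variant == variant, , drop = FALSE]
}

#' Split body mass into adipose and fat-free mass
#'
#' Reported masses use the integer-kg convention (adipose rounded, FFM as
#' the complement, so the two printed values always sum to the printed
#' mass); unrounded values are returned alongside.
#'
#' @param mass body mass, kg.
#' @param adiposeFraction unitless in `[0, 1]`.
#' @return List with `adipose_kg`, `ffm_kg` (integer-kg convention) and
#'   `adipose_raw_kg`, `ffm_raw_kg`.
#' @examples
#' compositionSplit(294, 0.247)  # 73 kg adipose, 221 kg FFM
#' @export
compositionSplit <- function(mass, adiposeFraction) {
  stopifnot(adiposeFraction >= 0, adiposeFraction <= 1)
  raw <- mass * adiposeFraction
  a <- round(raw)
  list(adipose_kg = a, ffm_kg = mass - a,
       adipose_raw_kg = raw, ffm_raw_kg = mass - raw)
}

#' Adipose fraction from the blubber shell of the truncated cones
#'
#' The blubber layer is modelled as the shell between the outer frusta
#' (radii from girths) and inner frusta whose radii are reduced by the mean
#' of the dorsal and lateral blubber thickness at each station. Shell volume
#' times lipid-rich blubber density (940 kg/m^3) gives blubber mass; the raw
#' fraction is blubber mass over body mass, passed through a linear
#' calibration to body-water-derived composition (`slope * raw + intercept`;
#' the shipped default is the identity, not the study calibration).
#'
#' @param m a [MorphometryRecord-class].
#' @param calibration numeric `c(slope, intercept)`.
#' @param blubberDensity kg/m^3 (default 940).
#' @param endRadiusFractions see [bodySAV()].
#' @return List with `fraction` (calibrated), `raw_fraction`, `blubber_kg`
#'   and `shell_volume_m3`.
#' @export
adiposeFromCones <- function(m, calibration = c(slope = 1, intercept = 0),
                             blubberDensity = 940,
                             endRadiusFractions = c(ear = 0.70, ankle = 0.60)) {
  stopifnot(is(m, "MorphometryRecord"))
  g <- .bodyBoundaries(m, endRadiusFractions)
  thick <- (m@blubberDorsal + m@blubberLateral) / 2 / 100   # m
  # end-boundary thickness taken from the adjacent station
  thickAll <- c(thick[1], thick, thick[6])
  inner <- g$radii - thickAll
  if (any(inner < 0))
    stop("blubber thickness exceeds body radius at station ",
         which(inner < 0)[1])
  h <- diff(g$bounds)
  outerV <- sum(coneGeometry(g$radii[-8], g$radii[-1], h)$volume)
  innerV <- sum(coneGeometry(inner[-8], inner[-1], h)$volume)
  shell <- outerV - innerV
  blubberKg <- shell * blubberDensity
  raw <- blubberKg / m@mass
  list(fraction = calibration[[1]] * raw + calibration[[2]],
       raw_fraction = raw, blubber_kg = blubberKg, shell_volume_m3 = shell)
}

#' Body composition from a morphometry record
#'
#' Convenience wrapper: adipose fraction from the blubber shell (or supplied
#' directly), composition split, and the three SA/V variants, bundled as a
#' [BodyComposition-class].
#'
#' @param m a [MorphometryRecord-class].
#' @param adiposeFraction if supplied, used directly instead of
#'   [adiposeFromCones()].
#' @param calibration,endRadiusFractions passed to [adiposeFromCones()] /
#'   [bodySAV()].
#' @return A [BodyComposition-class].
#' @export
bodyComposition <- function(m, adiposeFraction = NULL,
                            calibration = c(slope = 1, intercept = 0),
                            endRadiusFractions = c(ear = 0.70, ankle = 0.60)) {
  stopifnot(is(m, "MorphometryRecord"))
  if (is.null(adiposeFraction))
    adiposeFraction <- adiposeFromCones(m, calibration,
                                        endRadiusFractions = endRadiusFractions)$fraction
  split <- compositionSplit(m@mass, adiposeFraction)
  sav <- bodySAV(m, "all", endRadiusFractions)
  best <- sav[sav$variant == "best", ]
  new("BodyComposition", adiposeFraction = adiposeFraction,
      adiposeKg = split$adipose_kg, ffmKg = split$ffm_kg,
      surfaceArea = best$surface_area, volume = best$volume,
      savr = stats::setNames(sav$sav, sav$variant),
      raw = c(adipose_raw_kg = split$adipose_raw_kg,
              ffm_raw_kg = split$ffm_raw_kg))
}
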