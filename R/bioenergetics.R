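# Bioenergetics: tissue-energy partitioning, FMR integration over a linear
# mass trajectory, fever scenarios, blood-volume stores and fasting
# projections. Internal math is full precision; rounding to the printed
# conventions happens only at the reporting layer.

#' Energy content of lost (or gained) tissue
#'
#' Lean and lipid tissue contribute energy in proportion to their water-free
#' fraction times dry energy density: `lean_kg * 0.27 * 17.99` MJ and
#' `lipid_kg * 0.90 * 39.33` MJ by default.
#'
#' @param leanKg,lipidKg tissue masses, kg (>= 0 for losses; signs are
#'   propagated).
#' @param constants an [EnergyConstants-class].
#' @return List with `lean_MJ`, `lipid_MJ`, `total_MJ`, `lean_share_pct`.
#' @examples
#' tissueEnergy(21.0, 27.9)  # 102.0 + 987.6 = 1089.6 MJ, 9% lean
#' @export
tissueEnergy <- function(leanKg, lipidKg, constants = energyConstants()) {
  leanMJ <- leanKg * constants@leanDryFraction * constants@leanEnergyDensity
  lipidMJ <- lipidKg * constants@lipidDryFraction * constants@lipidEnergyDensity
  total <- leanMJ + lipidMJ
  list(lean_MJ = leanMJ, lipid_MJ = lipidMJ, total_MJ = total,
       lean_share_pct = if (total != 0) 100 * leanMJ / total else 0)
}

#' Field-metabolic-rate cost over a trip
#'
#' Integrates mass-specific FMR over a trip during which body mass declines
#' linearly between the endpoints; the integral of `fmr * m(t)` for linear
#' `m(t)` is exactly `fmr * days * (mStart + mEnd) / 2`.
#'
#' @param massStartKg,massEndKg endpoint masses, kg (> 0).
#' @param days trip duration (> 0).
#' @param fmr mass-specific field metabolic rate, kJ/kg/day.
#' @return Cost in MJ.
#' @examples
#' fmrCost(294, 245, 91)  # ~2210 MJ: what the trip costs with no intake
#' @export
fmrCost <- function(massStartKg, massEndKg, days,
                    fmr = energyConstants()@fmrBaseline) {
  stopifnot(days > 0, massStartKg > 0, massEndKg > 0)
  fmr * days * (massStartKg + massEndKg) / 2 / 1000
}

#' Fever-elevated field metabolic rate
#'
#' Endotherm metabolic rate rises 10-12.5% per degree C of body-temperature
#' elevation: `baseline * (1 + pctPerDegC * deltaT)`.
#'
#' @param baseline kJ/kg/day.
#' @param deltaT fever magnitude, degrees C (>= 0).
#' @param pctPerDegC fractional increase per degree (0.10 or 0.125).
#' @return Elevated FMR, kJ/kg/day.
#' @examples
#' feverFMR(90.1, 4, 0.10)    # 126.1
#' feverFMR(90.1, 4, 0.125)   # 135.2
#' @export
feverFMR <- function(baseline = energyConstants()@fmrBaseline, deltaT,
                     pctPerDegC) {
  if (any(deltaT < 0)) stop("deltaT must be non-negative")
  baseline * (1 + pctPerDegC * deltaT)
}

#' Energy cost of a febrile period
#'
#' Mass times elevated FMR times duration, in MJ. Defaults hold mass
#' constant at its value entering the febrile window (set `massEndKg` for a
#' linear trajectory instead).
#'
#' @param massKg body mass over the window, kg.
#' @param days length of the febrile window.
#' @param feverFmr elevated FMR, kJ/kg/day (see [feverFMR()]).
#' @param massEndKg optional end-of-window mass for a linear trajectory.
#' @return Cost in MJ.
#' @examples
#' feverCost(294, 14, feverFMR(90.1, 4, 0.125))  # ~556 MJ
#' @export
feverCost <- function(massKg, days, feverFmr, massEndKg = massKg) {
  stopifnot(massKg > 0, days > 0, feverFmr > 0)
  feverFmr * days * (massKg + massEndKg) / 2 / 1000
}

#' Blood volume from body mass
#'
#' Blood volume in the northern elephant seal is 20.2% of body mass, with
#' 1 kg of blood taken as 1 L.
#'
#' @param massKg body mass, kg (> 0).
#' @param fraction blood fraction of body mass (default 0.202).
#' @return Volume in litres.
#' @examples
#' bloodVolumeL(294)  # 59.4 L
#' @export
bloodVolumeL <- function(massKg, fraction = energyConstants()@bloodFraction) {
  stopifnot(all(massKg > 0))
  massKg * fraction
}

#' Project mass loss over a fast
#'
#' Constant-rate fasting loss: `loss = rate * days`.
#'
#' @param massKg starting mass, kg.
#' @param ratePerDay kg lost per day of fasting.
#' @param days fast length.
#' @return List with `loss_kg` and `final_mass_kg`.
#' @examples
#' fastingProjection(245, 2.37, 25)  # 59.25 kg lost, 185.75 kg remaining
#' @export
fastingProjection <- function(massKg, ratePerDay, days) {
  stopifnot(massKg > 0, ratePerDay > 0, days >= 0)
  loss <- ratePerDay * days
  if (loss >= massKg) stop("projection exceeds body mass")
  list(loss_kg = loss, final_mass_kg = massKg - loss)
}

#' Assemble a trip energy budget
#'
#' @param leanLossKg,lipidLossKg tissue lost over the trip, kg.
#' @param constants an [EnergyConstants-class].
#' @param scenarios named numeric of scenario costs in MJ (e.g. from
#'   [fmrCost()] or [feverCost()]).
#' @return An [EnergyBudget-class].
#' @export
energyBudget <- function(leanLossKg, lipidLossKg,
                         constants = energyConstants(),
                         scenarios = numeric(0)) {
  te <- tissueEnergy(leanLossKg, lipidLossKg, constants)
  new("EnergyBudget", leanLossKg = leanLossKg, lipidLossKg = lipidLossKg,
      leanMJ = te$lean_MJ, lipidMJ = te$lipid_MJ, totalMJ = te$total_MJ,
      leanSharePct = te$lean_share_pct, scenarios = scenarios)
}
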