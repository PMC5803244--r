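## Activation kinetics: depth-resolved production rates during irradiation
## and the build-up/decay closed form afterwards.

#' Depth-resolved production-rate profile
#'
#' Production rate of each positron emitter per depth bin during
#' irradiation: \eqn{R_i(z) = \Phi(z)\, n_O\, \sigma_i(E(z))\, \Delta z},
#' where \eqn{\Phi(z)} is the attenuated primary proton rate.  Zero beyond
#' the proton range and wherever \eqn{E(z)} is below the channel threshold.
#'
#' @param truth a \linkS4class{TruthXsecModel}.
#' @param map an \linkS4class{EnergyDepthMap} for the target material.
#' @param beam a \linkS4class{BeamSpec}.
#' @param material the target \linkS4class{Material}; must be the material
#'   the map was built for.
#' @param removalCrossSection flux-attenuation knob, barn
#'   (see \code{\link{fluxAttenuation}}).
#' @return List with \code{depth} (cm), \code{rate} (depth x isotope matrix,
#'   atoms/s per bin) and \code{isotopes}.
#' @examples
#' q <- standardMaterial("quartz"); b <- beamSpec(72, 30, 1800)
#' map <- buildEnergyDepthMap(q, b)
#' pr <- productionRateProfile(defaultTruthModel(), map, b, q)
#' @export
productionRateProfile <- function(truth, map, beam, material,
                                  removalCrossSection = 0.1) {
  if (!identical(map@materialName, material@name))
    stop("map was built for material '", map@materialName,
         "', not '", material@name, "'")
  z <- map@depthGrid
  dz <- if (length(z) > 1) z[2] - z[1] else stop("map grid too short")
  E <- map@energyAtDepth
  nO <- numberDensity(material, "O")
  phi <- protonRate(beam) *
    fluxAttenuation(material, z, removalCrossSection)
  isos <- names(truth@params)
  rate <- vapply(isos, function(iso) {
    s <- ifelse(E > 0, truthSigma(truth, iso, E), 0)
    phi * nO * s * .const$mbarn * dz
  }, numeric(length(z)))
  dimnames(rate) <- list(NULL, isos)
  list(depth = z, rate = rate, isotopes = isos)
}

#' Activity after irradiation
#'
#' Saturation build-up during a constant irradiation of duration
#' \code{tIrr}, then free decay:
#' \eqn{A(t) = R\,(1 - e^{-\lambda t_{irr}})\, e^{-\lambda t}} with t
#' measured from the end of irradiation.
#'
#' @param rate production rate R, atoms/s (vectorized).
#' @param component a \linkS4class{DecayComponent}.
#' @param tIrr irradiation duration, s.
#' @param t time after end of irradiation, s (vectorized, nonnegative).
#' @return Activity in Bq (decays/s).
#' @examples
#' activityAfterIrradiation(1000, decayComponents("O15")$O15, 1800, 122.2)
#' @export
activityAfterIrradiation <- function(rate, component, tIrr, t) {
  if (any(t < 0)) stop("t must be nonnegative (measured from end of irradiation)")
  lam <- component@decayConstant
  rate * (-expm1(-lam * tIrr)) * exp(-lam * t)
}

#' Atoms present at end of irradiation
#'
#' \eqn{N(0) = R (1 - e^{-\lambda t_{irr}}) / \lambda}; the amplitude
#' reference used by the decay decomposition.
#'
#' @inheritParams activityAfterIrradiation
#' @return Number of atoms.
#' @export
atomsAtEndOfIrradiation <- function(rate, component, tIrr) {
  lam <- component@decayConstant
  rate * (-expm1(-lam * tIrr)) / lam
}

## Decays of a component inside a window (t1, t2) after end of irradiation,
## per atom present at t = 0: e^{-lambda t1} - e^{-lambda t2}.
.windowDecayFraction <- function(component, t1, t2) {
  lam <- component@decayConstant
  exp(-lam * t1) - exp(-lam * t2)
}
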