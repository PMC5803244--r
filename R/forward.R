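## Deterministic 1-D activation forward model: predicted time-windowed
## positron depth profiles in water from a cross-section table set.

#' Forward positron depth profile from cross-section tables
#'
#' Predicts the positrons emitted per incident proton per depth bin inside
#' a time window after irradiation:
#' \deqn{\sum_i \sigma_i(E(z))\, n_O\, \Delta z\, \frac{\Phi(z)}{\Phi_0}
#' \frac{1 - e^{-\lambda_i t_{irr}}}{\lambda_i t_{irr}}
#' (e^{-\lambda_i t_1} - e^{-\lambda_i t_2})\, b_i,}
#' then smears with the PET Gaussian PSF (default 2.0 mm FWHM; the
#' smearing conserves the total).  Per-bin uncertainties propagate the
#' tables' \code{dsigma} columns.
#'
#' @param tables named list of \linkS4class{CrossSectionTable}; the energy
#'   coverage must reach the beam energy (an error lists any gap).
#' @param material the target \linkS4class{Material} (water for the PET
#'   benchmark).
#' @param beam a \linkS4class{BeamSpec}; the PET benchmark uses 69.2 MeV
#'   after the upstream degrader.
#' @param window (t1, t2) in s after end of irradiation, e.g.
#'   \code{c(15, 17) * 60}.
#' @param psfFwhm PSF FWHM in cm; 0 disables smearing.
#' @param depthStep grid step, cm.
#' @param removalCrossSection flux-attenuation knob, barn.
#' @param components decay components matching the table names.
#' @return A \linkS4class{ForwardProfile}.
#' @examples
#' \donttest{
#' tabs <- truthCrossSectionTables()
#' b <- beamSpec(69.2, 5, 5)
#' fp <- forwardPositronProfile(tabs, standardMaterial("water"), b,
#'                              window = c(15, 17) * 60)
#' locateProfilePeak(fp)
#' }
#' @export
forwardPositronProfile <- function(tables, material, beam, window,
                                   psfFwhm = 0.2, depthStep = 0.0133,
                                   removalCrossSection = 0.1,
                                   components = decayComponents(
                                     names(tables))) {
  if (diff(window) < 0) stop("window must be (t1, t2) with t2 >= t1")
  gaps <- names(tables)[vapply(tables, function(tb)
    max(tb@table$energy) < beam@initialEnergy - 1e-9, TRUE)]
  if (length(gaps))
    stop("cross-section coverage does not reach the beam energy (",
         beam@initialEnergy, " MeV) for: ", paste(gaps, collapse = ", "))
  map <- buildEnergyDepthMap(material, beam, depthStep = depthStep)
  z <- map@depthGrid
  E <- map@energyAtDepth
  dz <- z[2] - z[1]
  nO <- numberDensity(material, "O")
  phiRel <- fluxAttenuation(material, z, removalCrossSection)
  tIrr <- beam@irradiationDuration
  per <- vapply(names(tables), function(iso) {
    comp <- components[[iso]]
    lam <- comp@decayConstant
    s <- ifelse(E > 0, xsAt(tables[[iso]], pmin(E, max(E))), 0)
    s[E <= 0] <- 0
    s * .const$mbarn * nO * dz * phiRel *
      (-expm1(-lam * tIrr)) / (lam * tIrr) *
      .windowDecayFraction(comp, window[1], window[2]) *
      comp@branchingRatio
  }, numeric(length(z)))
  dimnames(per) <- list(NULL, names(tables))
  raw <- rowSums(per)
  varl <- vapply(names(tables), function(iso) {
    comp <- components[[iso]]
    lam <- comp@decayConstant
    ds <- ifelse(E > 0, xsAt(tables[[iso]], pmin(E, max(E)), "dsigma"), 0)
    (ds * .const$mbarn * nO * dz * phiRel *
       (-expm1(-lam * tIrr)) / (lam * tIrr) *
       .windowDecayFraction(comp, window[1], window[2]) *
       comp@branchingRatio)^2
  }, numeric(length(z)))
  sig <- sqrt(rowSums(varl))
  smeared <- if (psfFwhm > 0) .gaussianSmear(raw, z, psfFwhm) else raw
  new("ForwardProfile", depth = z, window = window, raw = raw,
      smeared = smeared, sigma = sig, perIsotope = per)
}

#' Ground-truth cross-section tables from the default truth model
#'
#' Tabulates the synthetic generator's truth curves as
#' \linkS4class{CrossSectionTable} objects (5-70 MeV), for closed-loop
#' forward-model tests when no measured table is supplied.
#'
#' @param model a \linkS4class{TruthXsecModel}.
#' @param energy tabulation grid, MeV.
#' @return Named list of \linkS4class{CrossSectionTable}.
#' @export
truthCrossSectionTables <- function(model = defaultTruthModel(),
                                    energy = seq(5, 70, by = 0.25)) {
  lapply(setNames(names(model@params), names(model@params)), function(iso)
    crossSectionTable(iso, energy, truthSigma(model, iso, energy),
                      meta = list(stage = "truth")))
}

#' Locate the peak of a forward profile
#'
#' Quadratic-interpolated argmax of the PSF-smeared profile.
#'
#' @param profile a \linkS4class{ForwardProfile}.
#' @return Depth in cm.
#' @export
locateProfilePeak <- function(profile) {
  y <- profile@smeared
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1e-300))
    stop("flat profile has no peak")
  .quadraticPeak(profile@depth, y)$x
}

#' Compare a predicted and a measured profile
#'
#' Per-bin z-scores \eqn{(pred - meas)/\sqrt{\sigma_{pred}^2 +
#' \sigma_{meas}^2}} on a common grid (the measured profile is resampled
#' with conserved totals if the grids differ), and the fraction of bins
#' within 1 sigma.  Bins with zero combined variance but nonzero
#' difference are flagged.
#'
#' @param predicted a \linkS4class{ForwardProfile}.
#' @param measured a \linkS4class{ForwardProfile} (e.g. from
#'   \code{\link{renderPetTruth}} with a variance attached, or read from
#'   TSV).
#' @param measuredSigma optional override of the measured uncertainties.
#' @return List with \code{z} (per-bin z-scores), \code{fractionWithin1},
#'   \code{flagged} (indices with inconsistent zero variance).
#' @export
compareProfiles <- function(predicted, measured, measuredSigma = NULL) {
  zp <- predicted@depth
  pm <- measured@smeared
  if (!isTRUE(all.equal(measured@depth, zp))) {
    dzp <- zp[2] - zp[1]; dzm <- measured@depth[2] - measured@depth[1]
    tot <- sum(pm)
    pm <- approx(measured@depth, pm / dzm, xout = zp, rule = 2)$y * dzp
    if (sum(pm) > 0) pm <- pm * tot / sum(pm)
  }
  sm <- if (!is.null(measuredSigma)) measuredSigma
        else if (length(measured@sigma) == length(pm)) measured@sigma
        else rep(0, length(pm))
  sp <- if (length(predicted@sigma)) predicted@sigma else rep(0, length(pm))
  v <- sp^2 + sm^2
  diffv <- predicted@smeared - pm
  z <- ifelse(v > 0, diffv / sqrt(v), ifelse(diffv == 0, 0, Inf))
  flagged <- which(v == 0 & diffv != 0)
  list(z = z, fractionWithin1 = mean(abs(z) <= 1), flagged = flagged)
}
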