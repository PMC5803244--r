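#' @import methods
#' @importFrom stats approx optimize rnorm rpois runif setNames integrate
#'   median qnorm pchisq lm.fit
#' @importFrom utils read.delim write.table head tail modifyList
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## Material
## ---------------------------------------------------------------------------

#' Target material
#'
#' Describes a homogeneous target: mass density, stoichiometric composition,
#' mean excitation energy (I-value) for the Bethe stopping power, and
#' refractive index for the Cherenkov threshold.
#'
#' @slot name character label.
#' @slot density mass density in g/cm^3.
#' @slot composition named numeric vector, atoms per formula unit
#'   (e.g. \code{c(Si = 1, O = 2)}).
#' @slot meanExcitationEnergy I-value in eV.
#' @slot refractiveIndex dimensionless; must exceed 1 for Cherenkov-capable
#'   materials.
#' @exportClass Material
setClass("Material",
  representation(
    name = "character",
    density = "numeric",
    composition = "numeric",
    meanExcitationEnergy = "numeric",
    refractiveIndex = "numeric"
  )
)

setValidity("Material", function(object) {
  msg <- character()
  if (length(object@density) != 1 || !is.finite(object@density) ||
      object@density <= 0)
    msg <- c(msg, "density must be a single positive number")
  if (is.null(names(object@composition)) || any(names(object@composition) == ""))
    msg <- c(msg, "composition must be a named vector of atoms per formula unit")
  if (any(object@composition <= 0))
    msg <- c(msg, "composition entries must be positive")
  if (!all(names(object@composition) %in% .elements$symbol))
    msg <- c(msg, "composition contains unknown elements")
  if (object@meanExcitationEnergy <= 0)
    msg <- c(msg, "meanExcitationEnergy must be positive (eV)")
  if (object@refractiveIndex < 1)
    msg <- c(msg, "refractiveIndex must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a Material
#'
#' @param name label.
#' @param density g/cm^3.
#' @param composition named numeric vector of atoms per formula unit.
#' @param meanExcitationEnergy I-value in eV.
#' @param refractiveIndex refractive index (1 for opaque/irrelevant media).
#' @return A \linkS4class{Material}.
#' @examples
#' material("water", 1.0, c(H = 2, O = 1), 75, 1.333)
#' @export
material <- function(name, density, composition, meanExcitationEnergy,
                     refractiveIndex = 1) {
  new("Material", name = name, density = density,
      composition = composition,
      meanExcitationEnergy = meanExcitationEnergy,
      refractiveIndex = refractiveIndex)
}

#' Built-in target materials
#'
#' Water (I = 75 eV), synthetic fused quartz SiO2 at 2.20 g/cm^3
#' (I = 139.2 eV, n = 1.458) and polyethylene at 0.94 g/cm^3 (I = 57.4 eV).
#' I-values are the ICRU recommendations.
#'
#' @param name one of "water", "quartz", "polyethylene".
#' @return A \linkS4class{Material}.
#' @examples
#' standardMaterial("quartz")
#' @export
standardMaterial <- function(name = c("water", "quartz", "polyethylene")) {
  name <- match.arg(name)
  switch(name,
    water = material("water", 1.000, c(H = 2, O = 1), 75.0, 1.333),
    quartz = material("quartz", 2.20, c(Si = 1, O = 2), 139.2, 1.458),
    polyethylene = material("polyethylene", 0.94, c(C = 1, H = 2), 57.4, 1.0)
  )
}

#' Molar mass of a material's formula unit
#' @param material a \linkS4class{Material}.
#' @return g/mol.
#' @export
molarMass <- function(material) {
  sum(material@composition * .elementA(names(material@composition)))
}

#' Electron density ratio Z/A of a material
#' @param material a \linkS4class{Material}.
#' @return dimensionless Z/A (per atomic mass unit).
#' @export
zOverA <- function(material) {
  sum(material@composition * .elementZ(names(material@composition))) /
    molarMass(material)
}

#' Atom number densities
#'
#' Number density of atoms of one element (or of all atoms) in the material.
#'
#' @param material a \linkS4class{Material}.
#' @param element element symbol, or NULL for the total over all elements.
#' @return atoms/cm^3.
#' @examples
#' numberDensity(standardMaterial("quartz"), "O")
#' @export
numberDensity <- function(material, element = NULL) {
  perFormula <- material@density * .const$Nav / molarMass(material)
  if (is.null(element)) return(perFormula * sum(material@composition))
  n <- material@composition[element]
  if (is.na(n)) 0 else unname(perFormula * n)
}

setMethod("show", "Material", function(object) {
  comp <- paste0(names(object@composition), object@composition, collapse = "")
  cat("Material ", object@name, " (", comp, "): ",
      object@density, " g/cm^3, I = ", object@meanExcitationEnergy,
      " eV, n = ", object@refractiveIndex, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## BeamSpec
## ---------------------------------------------------------------------------

#' Proton beam specification
#'
#' @slot initialEnergy MeV at the target entrance (after any degrader).
#' @slot current beam current in nA.
#' @slot irradiationDuration s.
#' @slot lateralFWHM length-2 numeric, beam FWHM in cm along the two lateral
#'   axes.
#' @exportClass BeamSpec
setClass("BeamSpec",
  representation(
    initialEnergy = "numeric",
    current = "numeric",
    irradiationDuration = "numeric",
    lateralFWHM = "numeric"
  )
)

setValidity("BeamSpec", function(object) {
  msg <- character()
  if (object@initialEnergy <= 0 || object@initialEnergy > 300)
    msg <- c(msg, "initialEnergy must be in (0, 300] MeV")
  if (object@irradiationDuration <= 0)
    msg <- c(msg, "irradiationDuration must be positive")
  if (object@current <= 0)
    msg <- c(msg, "current must be positive (nA)")
  if (length(object@lateralFWHM) != 2 || any(object@lateralFWHM <= 0))
    msg <- c(msg, "lateralFWHM must be two positive numbers (cm)")
  if (length(msg)) msg else TRUE
})

#' Construct a BeamSpec
#'
#' @param initialEnergy MeV.
#' @param current nA.
#' @param irradiationDuration s.
#' @param lateralFWHM beam FWHM (cm), recycled to length 2.
#' @return A \linkS4class{BeamSpec}.
#' @examples
#' beamSpec(72.0, 30, 1800, c(0.400, 0.246))
#' @export
beamSpec <- function(initialEnergy, current, irradiationDuration,
                     lateralFWHM = c(0.400, 0.246)) {
  new("BeamSpec", initialEnergy = initialEnergy, current = current,
      irradiationDuration = irradiationDuration,
      lateralFWHM = rep_len(lateralFWHM, 2))
}

#' Proton rate of a beam
#' @param beam a \linkS4class{BeamSpec}.
#' @return protons per second.
#' @export
protonRate <- function(beam) {
  beam@current * 1e-9 / .const$e_charge
}

setMethod("show", "BeamSpec", function(object) {
  cat("BeamSpec: ", object@initialEnergy, " MeV, ", object@current, " nA (",
      format(protonRate(object), digits = 4), " p/s), ",
      object@irradiationDuration, " s, FWHM ",
      paste(object@lateralFWHM, collapse = " x "), " cm\n", sep = "")
})

## ---------------------------------------------------------------------------
## EnergyDepthMap
## ---------------------------------------------------------------------------

#' Depth-to-energy map of a slowing-down proton beam
#'
#' Result of integrating dE/dz = -rho S(E) from the entrance face.  Holds the
#' requested bin-center grid plus a fine internal path used for accurate
#' interpolation and inversion, the accumulated Bohr straggling width, and
#' the CSDA range.
#'
#' @slot depthGrid requested depth grid (bin centers, cm).
#' @slot energyAtDepth MeV at each grid point (0 past the range).
#' @slot stragglingSigma accumulated energy-straggling sigma (MeV).
#' @slot csdaRange CSDA range (cm).
#' @slot fineDepth,fineEnergy,fineSigma internal fine-path tables.
#' @slot materialName,initialEnergy provenance.
#' @exportClass EnergyDepthMap
setClass("EnergyDepthMap",
  representation(
    depthGrid = "numeric",
    energyAtDepth = "numeric",
    stragglingSigma = "numeric",
    csdaRange = "numeric",
    fineDepth = "numeric",
    fineEnergy = "numeric",
    fineSigma = "numeric",
    materialName = "character",
    initialEnergy = "numeric"
  )
)

setValidity("EnergyDepthMap", function(object) {
  msg <- character()
  inR <- object@energyAtDepth > 0
  if (any(diff(object@energyAtDepth[inR]) >= 0))
    msg <- c(msg, "energy must be strictly decreasing inside the range")
  if (any(object@stragglingSigma < 0))
    msg <- c(msg, "straggling sigma must be nonnegative")
  if (any(diff(object@fineSigma) < -1e-12))
    msg <- c(msg, "straggling sigma must be nondecreasing in depth")
  if (object@csdaRange <= 0)
    msg <- c(msg, "csdaRange must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn buildEnergyDepthMap Depth grid accessor.
#' @export
depthGrid <- function(x) x@depthGrid

#' @describeIn buildEnergyDepthMap CSDA range accessor (cm).
#' @export
csdaRange <- function(map) map@csdaRange

setMethod("show", "EnergyDepthMap", function(object) {
  cat("EnergyDepthMap (", object@materialName, "): E0 = ",
      object@initialEnergy, " MeV, CSDA range = ",
      format(object@csdaRange, digits = 4), " cm, ",
      length(object@depthGrid), " depth bins\n", sep = "")
})

## ---------------------------------------------------------------------------
## DecayComponent
## ---------------------------------------------------------------------------

#' One positron-emitting decay component
#'
#' @slot isotope label ("O15", "N13", "C11", "O14").
#' @slot halfLife s.
#' @slot decayConstant 1/s, exactly ln(2)/halfLife.
#' @slot endpointEnergy positron endpoint kinetic energy, MeV.
#' @slot branchingRatio beta+ branching fraction in (0, 1].
#' @exportClass DecayComponent
setClass("DecayComponent",
  representation(
    isotope = "character",
    halfLife = "numeric",
    decayConstant = "numeric",
    endpointEnergy = "numeric",
    branchingRatio = "numeric"
  )
)

setValidity("DecayComponent", function(object) {
  msg <- character()
  if (abs(object@decayConstant * object@halfLife - log(2)) > 1e-12)
    msg <- c(msg, "decayConstant * halfLife must equal ln 2")
  if (object@branchingRatio <= 0 || object@branchingRatio > 1)
    msg <- c(msg, "branchingRatio must be in (0, 1]")
  if (object@endpointEnergy <= 0)
    msg <- c(msg, "endpointEnergy must be positive")
  if (length(msg)) msg else TRUE
})

#' Decay components of the oxygen-derived positron emitters
#'
#' Returns the library components for the requested isotopes with half-lives
#' 122.2 s (15O), 597.9 s (13N), 1222 s (11C) and optionally 70.62 s (14O).
#' 14O is excluded by default: its half-life is below the 120 s start of the
#' analysis window and its production cross section is small, so it is only
#' of interest as a nuisance component.
#'
#' @param isotopes character vector of isotope labels.
#' @return A named list of \linkS4class{DecayComponent} objects.
#' @examples
#' comps <- decayComponents()
#' halfLife(comps$C11)
#' @export
decayComponents <- function(isotopes = c("O15", "N13", "C11")) {
  i <- match(isotopes, .isotopeData$isotope)
  if (anyNA(i)) stop("unknown isotope(s): ",
                     paste(isotopes[is.na(i)], collapse = ", "))
  out <- lapply(i, function(k) {
    hl <- .isotopeData$half_life[k]
    new("DecayComponent",
        isotope = .isotopeData$isotope[k],
        halfLife = hl, decayConstant = log(2) / hl,
        endpointEnergy = .isotopeData$endpoint[k],
        branchingRatio = .isotopeData$branching[k])
  })
  names(out) <- isotopes
  out
}

#' @describeIn decayComponents Half-life accessor (s).
#' @param component a \linkS4class{DecayComponent}.
#' @export
halfLife <- function(component) component@halfLife

#' @describeIn decayComponents Decay-constant accessor (1/s).
#' @export
decayConstant <- function(component) component@decayConstant

#' @describeIn decayComponents Isotope label accessor.
#' @export
isotope <- function(component) component@isotope

setMethod("show", "DecayComponent", function(object) {
  cat("DecayComponent ", object@isotope, ": T1/2 = ", object@halfLife,
      " s, endpoint ", object@endpointEnergy, " MeV, BR ",
      object@branchingRatio, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## CCDConfig
## ---------------------------------------------------------------------------

#' Camera configuration for the synthetic Cherenkov imager
#'
#' Defaults match the imaging geometry: 133 um pixels, 5 s exposures on a
#' 5 s cadence starting 120 s after end of irradiation.
#'
#' @slot pixelPitch cm per pixel.
#' @slot exposure s per frame.
#' @slot frameTimes frame start times, s after end of irradiation.
#' @slot gain counts per detected photon.
#' @slot readNoiseSigma Gaussian read noise, counts.
#' @slot darkLevel mean dark counts per pixel per frame.
#' @slot depthExtent imaged depth extent, cm.
#' @slot lateralExtent imaged lateral extent, cm.
#' @exportClass CCDConfig
setClass("CCDConfig",
  representation(
    pixelPitch = "numeric",
    exposure = "numeric",
    frameTimes = "numeric",
    gain = "numeric",
    readNoiseSigma = "numeric",
    darkLevel = "numeric",
    depthExtent = "numeric",
    lateralExtent = "numeric"
  )
)

setValidity("CCDConfig", function(object) {
  msg <- character()
  if (object@exposure <= 0) msg <- c(msg, "exposure must be positive")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  if (any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (min(object@frameTimes) < 0)
    msg <- c(msg, "frameTimes must be nonnegative")
  if (object@readNoiseSigma < 0 || object@darkLevel < 0)
    msg <- c(msg, "noise levels must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a CCDConfig
#'
#' @param pixelPitch cm per pixel (default 0.0133).
#' @param exposure s (default 5).
#' @param frameTimes frame start times in s after end of irradiation;
#'   default a 5 s cadence over 120-3600 s.
#' @param gain counts per photon.
#' @param readNoiseSigma counts.
#' @param darkLevel counts.
#' @param depthExtent cm of target depth imaged.
#' @param lateralExtent cm of lateral field imaged.
#' @return A \linkS4class{CCDConfig}.
#' @examples
#' ccdConfig(depthExtent = 1, lateralExtent = 0.4)
#' @export
ccdConfig <- function(pixelPitch = 0.0133, exposure = 5,
                      frameTimes = seq(120, 3600 - 5, by = 5),
                      gain = 1, readNoiseSigma = 10, darkLevel = 100,
                      depthExtent = 3.5, lateralExtent = 1.0) {
  new("CCDConfig", pixelPitch = pixelPitch, exposure = exposure,
      frameTimes = frameTimes, gain = gain,
      readNoiseSigma = readNoiseSigma, darkLevel = darkLevel,
      depthExtent = depthExtent, lateralExtent = lateralExtent)
}

setMethod("show", "CCDConfig", function(object) {
  cat("CCDConfig: ", length(object@frameTimes), " frames x ",
      object@exposure, " s (t = ", min(object@frameTimes), "..",
      max(object@frameTimes) + object@exposure, " s), pixel ",
      object@pixelPitch * 1e4, " um, field ", object@depthExtent, " x ",
      object@lateralExtent, " cm\n", sep = "")
})
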