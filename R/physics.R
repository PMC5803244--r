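## Proton slowing-down physics: Bethe stopping power, depth-energy mapping,
## Bohr straggling, degrader and flux-attenuation corrections.

.E_FLOOR <- 0.5  # MeV, validity floor of the Bethe evaluation

#' Proton mass stopping power
#'
#' Bethe formula with the full maximum-energy-transfer kinematics and the
#' material's mean excitation energy; no shell or Barkas corrections (they
#' are sub-percent above a few MeV, the validity floor of this
#' implementation).
#'
#' @param material a \linkS4class{Material}.
#' @param energy proton kinetic energy, MeV (vectorized); must lie in
#'   [0.5, 300].
#' @return Mass stopping power in MeV cm^2/g.
#' @examples
#' stoppingPower(standardMaterial("water"), 70)
#' @export
stoppingPower <- function(material, energy) {
  if (any(energy < .E_FLOOR) || any(energy > 300))
    stop("stoppingPower: energy out of validity range [", .E_FLOOR,
         ", 300] MeV")
  kin <- .protonKinematics(energy)
  me <- .const$me_c2
  I <- material@meanExcitationEnergy * 1e-6  # eV -> MeV
  mr <- me / .const$mp_c2
  wmax <- 2 * me * kin$beta2gamma2 / (1 + 2 * kin$gamma * mr + mr^2)
  L <- 0.5 * log(2 * me * kin$beta2gamma2 * wmax / I^2) - kin$beta2
  .const$K * zOverA(material) * L / kin$beta2
}

## Bohr straggling accumulation rate d(sigma_E^2)/dz in MeV^2/cm, with the
## relativistic spin-0 factor (1 - beta^2/2)/(1 - beta^2).
.stragglingRate <- function(material, energy) {
  kin <- .protonKinematics(energy)
  .const$bohr * zOverA(material) * material@density *
    (1 - kin$beta2 / 2) / (1 - kin$beta2)
}

## Residual CSDA range below the Bethe floor, via the power-law range-energy
## approximation R ~ E^1.77 anchored at the floor stopping power.
.tailRange <- function(material, efloor = .E_FLOOR) {
  # dR/dE = 1/(rho S); R(E) = R(efloor) * (E/efloor)^p  =>
  # R(efloor) = efloor / (p * rho * S(efloor))
  p <- 1.77
  efloor / (p * material@density * stoppingPower(material, efloor))
}

#' Build a depth-to-energy map
#'
#' Integrates dE/dz = -rho S(E) from the beam energy with a 4th-order
#' Runge-Kutta scheme on an internal fine grid (refined so the energy change
#' per step never exceeds 2\% of E), accumulating the Bohr straggling
#' variance along the path.  The map is sampled onto the requested
#' bin-center grid and is invertible on its monotone domain.
#'
#' @param material a \linkS4class{Material}.
#' @param beam a \linkS4class{BeamSpec} (entrance energy).
#' @param depthStep output grid step in cm; default one camera pixel
#'   (0.0133 cm).
#' @param maxDepth extent of the output grid (cm); default the CSDA range.
#' @return An \linkS4class{EnergyDepthMap}.
#' @examples
#' map <- buildEnergyDepthMap(standardMaterial("water"), beamSpec(69.2, 5, 5))
#' csdaRange(map)
#' @export
buildEnergyDepthMap <- function(material, beam, depthStep = 0.0133,
                                maxDepth = NULL) {
  if (depthStep <= 0) stop("depthStep must be positive")
  E0 <- beam@initialEnergy
  rho <- material@density
  dEdz <- function(E) -rho * stoppingPower(material, E)

  ## adaptive fine integration to the Bethe floor
  z <- 0; E <- E0; s2 <- 0
  zs <- numeric(4096); Es <- numeric(4096); ss <- numeric(4096)
  n <- 1L; zs[1] <- 0; Es[1] <- E0; ss[1] <- 0
  h0 <- min(depthStep, 0.02)
  while (E > .E_FLOOR) {
    h <- min(h0, 0.02 * E / (rho * stoppingPower(material, E)))
    ## do not step past the floor
    k1 <- dEdz(E)
    if (E + h * k1 < .E_FLOOR) h <- max((.E_FLOOR - E) / k1 * 0.9, 1e-7)
    k2 <- dEdz(max(E + h / 2 * k1, .E_FLOOR))
    k3 <- dEdz(max(E + h / 2 * k2, .E_FLOOR))
    k4 <- dEdz(max(E + h * k3, .E_FLOOR))
    Emid <- max(E + h / 2 * k2, .E_FLOOR)
    Enew <- E + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    s2 <- s2 + h * .stragglingRate(material, Emid)
    z <- z + h
    E <- max(Enew, .E_FLOOR * 0.999)
    n <- n + 1L
    if (n > length(zs)) { # grow
      zs <- c(zs, numeric(length(zs)))
      Es <- c(Es, numeric(length(Es)))
      ss <- c(ss, numeric(length(ss)))
    }
    zs[n] <- z; Es[n] <- E; ss[n] <- s2
    if (E <= .E_FLOOR) break
  }
  zs <- zs[seq_len(n)]; Es <- Es[seq_len(n)]; ss <- sqrt(ss[seq_len(n)])
  range_cm <- zs[n] + .tailRange(material)

  if (is.null(maxDepth)) maxDepth <- range_cm
  grid <- seq(depthStep / 2, maxDepth, by = depthStep)
  Eg <- approx(zs, Es, xout = grid, rule = 1)$y
  Eg[is.na(Eg) | grid >= range_cm] <- 0
  sg <- approx(zs, ss, xout = grid, rule = 2)$y

  new("EnergyDepthMap", depthGrid = grid, energyAtDepth = Eg,
      stragglingSigma = sg, csdaRange = range_cm,
      fineDepth = zs, fineEnergy = Es, fineSigma = ss,
      materialName = material@name, initialEnergy = E0)
}

#' Energy at depth / depth at energy
#'
#' Interpolates the fine internal path of an \linkS4class{EnergyDepthMap};
#' both directions are consistent to well below the output grid step.
#'
#' @param map an \linkS4class{EnergyDepthMap}.
#' @param depth cm (vectorized); \code{energyAtDepth(map, 0)} is the beam
#'   energy.
#' @return MeV (0 beyond the range).
#' @export
energyAtDepth <- function(map, depth) {
  if (any(depth < 0)) stop("depth must be nonnegative")
  E <- approx(map@fineDepth, map@fineEnergy, xout = depth, rule = 1)$y
  E[is.na(E)] <- 0
  E
}

#' @rdname energyAtDepth
#' @param energy MeV (vectorized), within (floor, beam energy].
#' @return \code{depthAtEnergy}: depth in cm where the beam has slowed to
#'   \code{energy}.
#' @export
depthAtEnergy <- function(map, energy) {
  if (any(energy > map@initialEnergy + 1e-9))
    stop("energy above the beam energy")
  approx(rev(map@fineEnergy), rev(map@fineDepth), xout = energy, rule = 2)$y
}

#' Straggling width at depth
#'
#' Accumulated Bohr energy-straggling sigma, the energy resolution attached
#' to cross-section points extracted at this depth.
#'
#' @param map an \linkS4class{EnergyDepthMap}.
#' @param depth cm (vectorized).
#' @return MeV.
#' @export
stragglingAtDepth <- function(map, depth) {
  approx(map@fineDepth, map@fineSigma, xout = depth, rule = 2)$y
}

#' Slow a beam through an upstream slab
#'
#' Exit energy of the beam after a degrader slab, e.g. the 3 mm polyethylene
#' used to slow 72.0 MeV protons to 69.2 MeV before a water target.
#'
#' @param beam a \linkS4class{BeamSpec}.
#' @param slabMaterial a \linkS4class{Material}.
#' @param thickness slab thickness in cm; must be less than the beam's CSDA
#'   range in the slab.
#' @return Exit energy in MeV.
#' @examples
#' degradeThroughSlab(beamSpec(72, 30, 1800),
#'                    standardMaterial("polyethylene"), 0.3)
#' @export
degradeThroughSlab <- function(beam, slabMaterial, thickness) {
  if (thickness == 0) return(beam@initialEnergy)
  if (thickness < 0) stop("thickness must be nonnegative")
  map <- buildEnergyDepthMap(slabMaterial, beam,
                             depthStep = min(0.005, thickness / 4))
  if (thickness >= map@csdaRange)
    stop("proton stops inside the slab (CSDA range ",
         format(map@csdaRange, digits = 4), " cm < thickness ", thickness,
         " cm)")
  E <- energyAtDepth(map, thickness)
  if (E <= .E_FLOOR)
    stop("proton exits the slab below the validity floor")
  E
}

#' Primary proton flux attenuation
#'
#' Fraction of primary protons surviving nuclear removal down to a depth,
#' \eqn{\Phi(z)/\Phi_0 = \exp(-n_{tot}\,\sigma_{rem}\,z)} with the total atom
#' number density.  The default removal cross section (0.1 barn) gives about
#' 1\%/cm in water at therapy energies; it is a configurable knob, not a
#' fitted quantity.
#'
#' @param material a \linkS4class{Material}.
#' @param depth cm (vectorized, nonnegative).
#' @param removalCrossSection barn per atom.
#' @return Surviving fraction in (0, 1].
#' @examples
#' fluxAttenuation(standardMaterial("water"), 1)
#' @export
fluxAttenuation <- function(material, depth, removalCrossSection = 0.1) {
  if (any(depth < 0)) stop("depth must be nonnegative")
  if (removalCrossSection < 0)
    stop("removal cross section must be nonnegative")
  exp(-numberDensity(material) * removalCrossSection * .const$barn * depth)
}
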