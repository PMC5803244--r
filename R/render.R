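## Synthetic EM-CCD frame stacks and synthetic PET positron profiles with
## known ground truth.

## Lateral beam profile on the camera's row grid: Gaussian of the beam FWHM
## centered in the field, normalized to unit sum.
.lateralProfile <- function(ccd, beam) {
  ny <- max(3L, round(ccd@lateralExtent / ccd@pixelPitch))
  y <- (seq_len(ny) - (ny + 1) / 2) * ccd@pixelPitch
  sd <- beam@lateralFWHM[2] / (2 * sqrt(2 * log(2)))
  w <- exp(-y^2 / (2 * sd^2))
  list(y = y, w = w / sum(w))
}

#' Render a synthetic Cherenkov frame stack
#'
#' Expected counts per frame are the per-isotope yield-weighted decays in
#' the exposure window (exact analytic integral of \eqn{e^{-\lambda t}}
#' over each frame; 15O decays appreciably within a 5 s exposure, so
#' midpoint sampling would bias it), blurred along depth with the isotope's
#' positron-range kernel, spread laterally over a Gaussian of the beam
#' FWHM, scaled by \code{photonScale} (the counts scale of the camera is
#' arbitrary) and offset by the dark level.  Poisson shot noise is applied
#' to the expected photon count, then multiplied by the gain and smeared
#' with Gaussian read noise.  The same seed reproduces the stack bit for
#' bit.
#'
#' @param production output of \code{\link{productionRateProfile}}.
#' @param components named list of \linkS4class{DecayComponent} matching
#'   the production isotopes.
#' @param beam a \linkS4class{BeamSpec}.
#' @param ccd a \linkS4class{CCDConfig}.
#' @param kernels named list of \linkS4class{BlurKernel}, unit area, one
#'   per isotope.
#' @param yieldFactors named numeric vector of relative photons per decay.
#' @param photonScale detection probability per emitted Cherenkov photon;
#'   sets the (otherwise arbitrary) counts scale.  The default 3e-5 is the
#'   geometric acceptance of the described camera: an f/1.4 lens of 16 mm
#'   focal length at 50 cm subtends a solid-angle fraction of about
#'   3.3e-5, times quantum efficiency and optical transmission ~0.8.
#' @param noise logical; FALSE renders the noise-free expectation (dark
#'   level still added).
#' @param seed integer seed for the noise.
#' @return A \linkS4class{CherenkovStack}.
#' @export
renderCherenkovStack <- function(production, components, beam, ccd, kernels,
                                 yieldFactors, photonScale = 3e-5,
                                 noise = TRUE, seed = 1L) {
  if (min(ccd@frameTimes) < 0)
    stop("frame window overlaps t < 0 (before end of irradiation)")
  isos <- production$isotopes
  if (!all(isos %in% names(components)) || !all(isos %in% names(kernels)) ||
      !all(isos %in% names(yieldFactors)))
    stop("components, kernels and yieldFactors must cover isotopes: ",
         paste(isos, collapse = ", "))
  zf <- production$depth
  nz <- min(length(zf), round(ccd@depthExtent / ccd@pixelPitch))
  lat <- .lateralProfile(ccd, beam)
  ny <- length(lat$y)
  t1 <- ccd@frameTimes
  t2 <- t1 + ccd@exposure
  nt <- length(t1)

  ## one column per isotope: vectorized lateral x depth image and frame
  ## decay factors; the stack is their single matrix product
  imgCols <- vapply(isos, function(iso) {
    n0 <- atomsAtEndOfIrradiation(production$rate[, iso],
                                  components[[iso]],
                                  beam@irradiationDuration)
    depthSig <- convolveProfile(n0, kernels[[iso]])[seq_len(nz)] *
      yieldFactors[[iso]] * photonScale
    as.vector(outer(lat$w, depthSig))
  }, numeric(ny * nz))
  timeRows <- matrix(unlist(lapply(isos, function(iso)
    .windowDecayFraction(components[[iso]], t1, t2))),
    nrow = length(isos), ncol = nt, byrow = TRUE)
  expected <- array(imgCols %*% timeRows + ccd@darkLevel,
                    dim = c(ny, nz, nt))

  if (noise) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    counts <- ccd@gain *
      array(rpois(length(expected), expected), dim = dim(expected)) +
      array(rnorm(length(expected), 0, ccd@readNoiseSigma),
            dim = dim(expected))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  } else {
    counts <- ccd@gain * expected
  }

  .cherenkovStack(counts, t1, ccd@exposure, ccd@pixelPitch,
                  meta = list(seed = seed, stage = "simulate",
                              noise = noise, gain = ccd@gain,
                              readNoiseSigma = ccd@readNoiseSigma,
                              darkLevel = ccd@darkLevel))
}

#' Render synthetic dark frames
#'
#' Frames with no Cherenkov signal: Poisson dark level plus Gaussian read
#' noise, used by \code{\link{subtractBackground}}.
#'
#' @param ccd a \linkS4class{CCDConfig}.
#' @param nFrames number of dark frames.
#' @param beam a \linkS4class{BeamSpec} (geometry only).
#' @param seed integer seed.
#' @return A \linkS4class{CherenkovStack}.
#' @export
renderDarkFrames <- function(ccd, nFrames = 20, beam = beamSpec(72, 30, 1800),
                             seed = 2L) {
  lat <- .lateralProfile(ccd, beam)
  nz <- round(ccd@depthExtent / ccd@pixelPitch)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  dk <- ccd@gain *
    array(rpois(length(lat$y) * nz * nFrames, ccd@darkLevel),
          dim = c(length(lat$y), nz, nFrames)) +
    array(rnorm(length(lat$y) * nz * nFrames, 0, ccd@readNoiseSigma),
          dim = c(length(lat$y), nz, nFrames))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  .cherenkovStack(dk, seq_len(nFrames), 1, ccd@pixelPitch,
                  meta = list(seed = seed, stage = "dark",
                              gain = ccd@gain,
                              readNoiseSigma = ccd@readNoiseSigma,
                              darkLevel = ccd@darkLevel))
}

#' Synthetic PET truth profile
#'
#' Positrons emitted in a time window per depth bin, from the generator's
#' production profile: decays in the window weighted by the beta+ branching
#' ratio, optionally smeared with the PET Gaussian PSF (default 2.0 mm
#' FWHM).  Reported per incident proton.
#'
#' @param production output of \code{\link{productionRateProfile}}.
#' @param components named list of \linkS4class{DecayComponent}.
#' @param beam a \linkS4class{BeamSpec}.
#' @param window (t1, t2) in s after end of irradiation.
#' @param psfFwhm Gaussian PSF FWHM in cm; 0 disables smearing.
#' @return A \linkS4class{ForwardProfile}.
#' @export
renderPetTruth <- function(production, components, beam, window,
                           psfFwhm = 0.2) {
  if (any(window < 0)) stop("window outside the simulated span (t >= 0)")
  if (diff(window) < 0) stop("window must be increasing")
  isos <- production$isotopes
  z <- production$depth
  per <- vapply(isos, function(iso) {
    comp <- components[[iso]]
    n0 <- atomsAtEndOfIrradiation(production$rate[, iso], comp,
                                  beam@irradiationDuration)
    n0 * .windowDecayFraction(comp, window[1], window[2]) *
      comp@branchingRatio
  }, numeric(length(z)))
  dimnames(per) <- list(NULL, isos)
  nProtons <- protonRate(beam) * beam@irradiationDuration
  per <- per / nProtons
  raw <- rowSums(per)
  smeared <- if (psfFwhm > 0) .gaussianSmear(raw, z, psfFwhm) else raw
  new("ForwardProfile", depth = z, window = window, raw = raw,
      smeared = smeared, sigma = numeric(length(raw)), perIsotope = per)
}

#' Synthetic noisy PET measurement
#'
#' A counting-noise realization of \code{\link{renderPetTruth}}: the
#' expected positron counts per bin (truth times the number of incident
#' protons times a detection efficiency) are Poisson-sampled and converted
#' back to positrons per incident proton, with the matching per-bin
#' counting sigma attached.
#'
#' @inheritParams renderPetTruth
#' @param efficiency detected fraction per emitted positron.
#' @param seed integer seed.
#' @return A \linkS4class{ForwardProfile} with a \code{sigma} slot.
#' @export
renderPetMeasurement <- function(production, components, beam, window,
                                 psfFwhm = 0.2, efficiency = 0.01,
                                 seed = 1L) {
  truth <- renderPetTruth(production, components, beam, window, psfFwhm)
  nProtons <- protonRate(beam) * beam@irradiationDuration
  mu <- truth@smeared * nProtons * efficiency
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  counts <- rpois(length(mu), mu)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  est <- counts / (nProtons * efficiency)
  sig <- sqrt(pmax(counts, 1)) / (nProtons * efficiency)
  new("ForwardProfile", depth = truth@depth, window = window,
      raw = est, smeared = est, sigma = sig,
      perIsotope = truth@perIsotope)
}

## Total-conserving Gaussian smearing on a uniform grid.
.gaussianSmear <- function(profile, z, fwhm) {
  dz <- z[2] - z[1]
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(5 * sd / dz)
  x <- (-half:half) * dz
  w <- exp(-x^2 / (2 * sd^2))
  k <- new("BlurKernel", isotope = "psf", scale = sd, step = dz,
           weights = w / sum(w))
  convolveProfile(profile, k)
}
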