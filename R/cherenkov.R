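## Cherenkov light model: per-isotope yield factors from the beta+ spectrum
## and the Frank-Tamm photon count, positron-range blur kernels, and
## Richardson-Lucy deconvolution of resolved depth profiles.

## Allowed beta+ spectrum shape (statistical factor only, no Fermi
## function): N(T) dT ~ p E (Q - T)^2, with p, E the positron momentum and
## total energy in units of me c^2.
.betaSpectrumDensity <- function(Tkin, endpoint) {
  me <- .const$me_c2
  E <- Tkin + me
  p <- sqrt(pmax(E^2 - me^2, 0))
  d <- p * E * (endpoint - Tkin)^2
  d[Tkin < 0 | Tkin > endpoint] <- 0
  d
}

## Cherenkov threshold kinetic energy for refractive index n: beta > 1/n.
.cherenkovThreshold <- function(n) {
  if (n <= 1) return(Inf)
  .const$me_c2 * (1 / sqrt(1 - 1 / n^2) - 1)
}

## Frank-Tamm photon count per unit path in a wavelength band (photons/cm):
## dN/dx = 2 pi alpha (1/l1 - 1/l2) (1 - 1/(beta^2 n^2)).
.frankTammWeight <- function(Tkin, n, band_nm) {
  me <- .const$me_c2
  gamma <- 1 + Tkin / me
  beta2 <- 1 - 1 / gamma^2
  w <- 2 * pi * .const$alpha * (1 / (band_nm[1] * 1e-7) -
                                1 / (band_nm[2] * 1e-7)) *
    (1 - 1 / (beta2 * n^2))
  pmax(w, 0)
}

#' Relative Cherenkov light yield of a decay component
#'
#' Integrates a simplified allowed beta+ spectrum above the Cherenkov
#' threshold kinetic energy of the material, weighting each emission energy
#' by the Frank-Tamm photon count per unit path over a wavelength band
#' (default 400-800 nm, camera-typical).  The result is a relative
#' photons-per-decay factor: higher endpoint energies give larger factors.
#' The factor is normalized per decay (branching ratio included).
#'
#' @param component a \linkS4class{DecayComponent}.
#' @param material a \linkS4class{Material}; its refractive index sets the
#'   threshold.
#' @param band wavelength band in nm, length 2.
#' @param relTol quadrature tolerance.
#' @return Relative photons per decay (arbitrary common scale).  0, with a
#'   warning, if the endpoint is below the Cherenkov threshold.
#' @examples
#' cherenkovYieldFactor(decayComponents("O15")$O15, standardMaterial("quartz"))
#' @export
cherenkovYieldFactor <- function(component, material, band = c(400, 800),
                                 relTol = 1e-8) {
  thr <- .cherenkovThreshold(material@refractiveIndex)
  Q <- component@endpointEnergy
  if (Q <= thr) {
    warning("endpoint of ", component@isotope,
            " is below the Cherenkov threshold (", format(thr, digits = 3),
            " MeV); yield factor 0")
    return(0)
  }
  num <- integrate(function(T)
    .betaSpectrumDensity(T, Q) *
      .frankTammWeight(T, material@refractiveIndex, band),
    thr, Q, rel.tol = relTol)$value
  den <- integrate(function(T) .betaSpectrumDensity(T, Q),
                   0, Q, rel.tol = relTol)$value
  component@branchingRatio * num / den
}

#' Mean energy of the allowed beta+ spectrum
#' @param component a \linkS4class{DecayComponent}.
#' @return MeV.
#' @export
meanBetaEnergy <- function(component) {
  Q <- component@endpointEnergy
  num <- integrate(function(T) T * .betaSpectrumDensity(T, Q), 0, Q)$value
  den <- integrate(function(T) .betaSpectrumDensity(T, Q), 0, Q)$value
  num / den
}

## Empirical electron CSDA range (Katz-Penfold), g/cm^2, E in MeV.
.positronCsdaRange <- function(E) {
  0.412 * E^(1.265 - 0.0954 * log(E))
}

#' Build a positron-range blur kernel
#'
#' Symmetric double-exponential (Laplacian) kernel
#' \eqn{k(z) \propto e^{-|z|/L}} discretized on the depth grid and
#' renormalized to unit area.  The characteristic length L is a configurable
#' fraction (default 0.5) of the mean positron CSDA range in the material,
#' evaluated at the mean energy of the component's beta+ spectrum.
#'
#' @param component a \linkS4class{DecayComponent}.
#' @param material a \linkS4class{Material}.
#' @param depthStep grid step, cm.
#' @param scaleFactor L as a fraction of the mean positron CSDA range.
#' @param nGrid number of grid points of the profile the kernel will act
#'   on; the kernel is truncated at 8 e-foldings and must fit the grid.
#' @return A \linkS4class{BlurKernel}.  \code{scaleFactor = 0} yields a
#'   discrete delta.
#' @examples
#' buildBlurKernel(decayComponents("O15")$O15, standardMaterial("quartz"),
#'                 0.0133)
#' @export
buildBlurKernel <- function(component, material, depthStep,
                            scaleFactor = 0.5, nGrid = Inf) {
  L <- scaleFactor * .positronCsdaRange(meanBetaEnergy(component)) /
    material@density
  if (L < depthStep / 100) {
    return(new("BlurKernel", isotope = component@isotope, scale = 0,
               step = depthStep, weights = 1))
  }
  half <- ceiling(8 * L / depthStep)
  if (is.finite(nGrid) && (2 * half + 1) > 2 * nGrid - 1)
    stop("blur kernel (", 2 * half + 1, " taps) is wider than the grid")
  x <- (-half:half) * depthStep
  ## integrate the Laplacian density over each bin for exact discretization
  lo <- x - depthStep / 2; hi <- x + depthStep / 2
  cdf <- function(z) ifelse(z < 0, 0.5 * exp(z / L), 1 - 0.5 * exp(-z / L))
  w <- cdf(hi) - cdf(lo)
  w <- w / sum(w)
  w <- (w + rev(w)) / 2  # enforce exact symmetry against rounding
  new("BlurKernel", isotope = component@isotope, scale = L,
      step = depthStep, weights = w)
}

## Column-normalized convolution matrix of a kernel on an n-point grid.
## Column normalization makes convolution conserve the total even where the
## kernel is truncated by the grid edge.
.kernelMatrix <- function(kernel, n) {
  w <- kernel@weights
  half <- (length(w) - 1) / 2
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- (j - half):(j + half)
    ok <- i >= 1 & i <= n
    K[i[ok], j] <- w[ok] / sum(w[ok])
  }
  K
}

#' Convolve a depth profile with a blur kernel
#'
#' Edge-renormalized discrete convolution (total conserved).
#'
#' @param profile numeric vector on the depth grid.
#' @param kernel a \linkS4class{BlurKernel}.
#' @return Blurred profile, same length.
#' @export
convolveProfile <- function(profile, kernel) {
  as.numeric(.kernelMatrix(kernel, length(profile)) %*% profile)
}

#' Richardson-Lucy deconvolution of a depth profile
#'
#' Multiplicative Richardson-Lucy iteration with a fixed iteration count.
#' The input is clipped at zero (low-SNR bins can go slightly negative
#' after background subtraction); the output is nonnegative and the total
#' count is conserved to machine precision at every iteration.
#'
#' @param profile numeric vector, NA-free.
#' @param kernel a \linkS4class{BlurKernel}.
#' @param nIter iterations (default 50).
#' @param regularization small floor added to the re-blurred estimate to
#'   stabilize empty bins.
#' @return Deblurred profile.
#' @examples
#' k <- buildBlurKernel(decayComponents("O15")$O15,
#'                      standardMaterial("quartz"), 0.0133)
#' x <- c(rep(0, 20), 100, rep(0, 20))
#' y <- deconvolveProfile(convolveProfile(x, k), k)
#' @export
deconvolveProfile <- function(profile, kernel, nIter = 50,
                              regularization = 1e-12) {
  if (any(!is.finite(profile))) stop("profile contains NA/NaN")
  d <- pmax(profile, 0)
  if (sum(d) == 0) return(d)
  n <- length(d)
  K <- .kernelMatrix(kernel, n)
  u <- rep(sum(d) / n, n)
  for (it in seq_len(nIter)) {
    est <- as.numeric(K %*% u)
    ratio <- d / pmax(est, regularization * max(est))
    u <- u * as.numeric(crossprod(K, ratio))
    u <- u * sum(d) / sum(u)  # guard count conservation against round-off
  }
  u
}
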