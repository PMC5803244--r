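## Cross-section extraction: invert activation build-up, deblur, map depth
## to energy, and normalize to the archival anchor.

#' Invert the activation build-up
#'
#' Converts a resolved per-isotope amplitude profile (yield-weighted atoms
#' at end of irradiation) into a relative production-rate profile:
#' \deqn{R_i(z) \propto a_i(z)\,\lambda_i / [y_i (1 - e^{-\lambda_i
#' t_{irr}})]} with the saturation factor guarded against underflow at
#' small \eqn{\lambda t_{irr}}.  Uncertainties scale identically.
#'
#' @param profile numeric amplitude profile.
#' @param component a \linkS4class{DecayComponent}.
#' @param beam a \linkS4class{BeamSpec} (supplies the irradiation
#'   duration).
#' @param yieldFactor the isotope's relative Cherenkov yield.
#' @param sigma optional amplitude uncertainties.
#' @return List with \code{rate} and \code{sigma} (relative units).
#' @export
amplitudesToProduction <- function(profile, component, beam, yieldFactor,
                                   sigma = NULL) {
  lam <- component@decayConstant
  tIrr <- beam@irradiationDuration
  sat <- -expm1(-lam * tIrr)  # accurate for lambda*tIrr ~ 0
  f <- lam / (yieldFactor * sat)
  list(rate = profile * f,
       sigma = if (is.null(sigma)) NULL else sigma * f)
}

#' Map a production profile onto the energy axis
#'
#' \eqn{\sigma_{rel}(E(z)) = R(z) / (n_O\, \Phi_{rel}(z)\, \Delta z)}.
#' Each point carries the local straggling sigma as its energy
#' uncertainty.  Bins past the proton range (where the depth-energy map is
#' not invertible) are dropped with a message, the output is restricted to
#' the requested energy band (default 5-70 MeV), and the rows are sorted
#' by increasing energy.
#'
#' @param rate production-rate profile on the map's depth grid (relative).
#' @param map an \linkS4class{EnergyDepthMap}.
#' @param material the target \linkS4class{Material}.
#' @param sigma per-bin uncertainties of \code{rate} (or NULL).
#' @param mask logical vector of bins to exclude.
#' @param removalCrossSection flux-correction knob, barn; NULL disables
#'   the correction.
#' @param energyRange keep only points inside this band (MeV).
#' @return data.frame (energy, denergy, sigma, dsigma) in relative units.
#' @export
toEnergyAxis <- function(rate, map, material, sigma = NULL, mask = NULL,
                         removalCrossSection = 0.1,
                         energyRange = c(5, 70)) {
  z <- map@depthGrid
  stopifnot(length(rate) == length(z))
  dz <- z[2] - z[1]
  E <- map@energyAtDepth
  keep <- E > .E_FLOOR
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " depth bins past the proton range dropped")
  if (!is.null(mask)) keep <- keep & !mask
  phiRel <- if (is.null(removalCrossSection)) rep(1, length(z))
            else fluxAttenuation(material, z, removalCrossSection)
  nO <- numberDensity(material, "O")
  srel <- rate / (nO * phiRel * dz)
  out <- data.frame(energy = E[keep],
                    denergy = stragglingAtDepth(map, z[keep]),
                    sigma = srel[keep],
                    dsigma = if (is.null(sigma)) 0
                             else (sigma / (nO * phiRel * dz))[keep])
  out <- out[out$energy >= energyRange[1] & out$energy <= energyRange[2], ]
  out <- out[order(out$energy), ]
  ## collapse duplicate energies from grid round-off
  out <- out[!duplicated(signif(out$energy, 10)), ]
  rownames(out) <- NULL
  out
}

## Quadratic interpolation of the maximum around the discrete argmax.
.quadraticPeak <- function(x, y) {
  i <- which.max(y)
  if (i == 1 || i == length(y))
    return(list(x = x[i], y = y[i]))
  x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  fit <- lm.fit(cbind(1, x3, x3^2), y3)
  b <- fit$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) return(list(x = x[i], y = y[i]))
  xp <- -b[2] / (2 * b[3])
  list(x = unname(xp), y = unname(b[1] + b[2] * xp + b[3] * xp^2))
}

#' Normalize relative cross-section tables to an archival anchor
#'
#' Fixes the single arbitrary scale of the Cherenkov measurement: the
#' anchor isotope's maximum (located by quadratic interpolation around the
#' discrete argmax, for grid-step robustness) is set equal to the archival
#' anchor value, and the same factor is applied to every isotope
#' simultaneously.  The anchor's relative uncertainty is added in
#' quadrature to every point.  The default anchor is the archival
#' 16O(p,x)15O maximum, 76.8 mbarn +/- 2.45\% at 35 MeV.
#'
#' @param tables named list of relative tables (data.frames with energy,
#'   denergy, sigma, dsigma), as produced by \code{\link{toEnergyAxis}}.
#' @param anchor list with \code{isotope}, \code{energy} (MeV),
#'   \code{sigma} (mbarn), \code{relUncertainty}.
#' @param meta provenance list stored on the output tables.
#' @return Named list of \linkS4class{CrossSectionTable} in mbarn.
#' @export
normalizeToAnchor <- function(tables,
                              anchor = list(isotope = "O15", energy = 35,
                                            sigma = 76.8,
                                            relUncertainty = 0.0245),
                              meta = list()) {
  ref <- tables[[anchor$isotope]]
  if (is.null(ref)) stop("anchor isotope ", anchor$isotope,
                         " not among the tables")
  if (!nrow(ref) || all(ref$sigma == 0))
    stop("anchor isotope's relative curve is empty or all zero")
  pk <- .quadraticPeak(ref$energy, ref$sigma)
  if (abs(pk$x - anchor$energy) > 2)
    warning("relative ", anchor$isotope, " maximum at ",
            format(pk$x, digits = 4), " MeV is more than 2 MeV from the ",
            "anchor energy ", anchor$energy, " MeV")
  scale <- anchor$sigma / pk$y
  lapply(setNames(names(tables), names(tables)), function(iso) {
    tb <- tables[[iso]]
    sig <- tb$sigma * scale
    stat <- tb$dsigma * scale
    dsig <- sqrt(stat^2 + (anchor$relUncertainty * sig)^2)
    crossSectionTable(iso, tb$energy, sig, tb$denergy, dsig,
                      meta = c(meta, list(anchor = anchor,
                                          scaleFactor = scale)))
  })
}

#' Rebin a cross-section table to the straggling resolution
#'
#' Variable-width energy bins matched to the local straggling sigma (the
#' physical energy resolution), averaging points inverse-variance weighted.
#'
#' @param x a \linkS4class{CrossSectionTable} (or bare data.frame).
#' @param widthFactor bin width as a multiple of the local straggling
#'   sigma.
#' @return Same class as the input, rebinned.
#' @export
rebinToStraggling <- function(x, widthFactor = 1) {
  tb <- if (is(x, "CrossSectionTable")) x@table else x
  edges <- numeric(0)
  e <- min(tb$energy)
  emax <- max(tb$energy)
  while (e < emax) {
    edges <- c(edges, e)
    de <- approx(tb$energy, pmax(tb$denergy, 1e-3), xout = e, rule = 2)$y
    e <- e + max(widthFactor * de, 1e-3)
  }
  edges <- c(edges, emax + 1e-9)
  bin <- cut(tb$energy, edges, right = FALSE, labels = FALSE)
  agg <- function(v, w) vapply(split(seq_along(v), bin), function(i)
    sum(v[i] * w[i]) / sum(w[i]), 0)
  w <- ifelse(tb$dsigma > 0, 1 / tb$dsigma^2, 1)
  out <- data.frame(energy = agg(tb$energy, w),
                    denergy = agg(tb$denergy, w),
                    sigma = agg(tb$sigma, w),
                    dsigma = vapply(split(seq_along(w), bin), function(i)
                      sqrt(1 / sum(w[i])), 0))
  out <- out[order(out$energy), ]
  rownames(out) <- NULL
  if (is(x, "CrossSectionTable"))
    crossSectionTable(x@isotope, out$energy, out$sigma, out$denergy,
                      out$dsigma, meta = x@meta)
  else out
}

#' Extract cross sections from a decomposed depth-profile series
#'
#' Convenience chain for the analysis stages downstream of the
#' decomposition: per-isotope build-up inversion, Richardson-Lucy
#' deblurring with each isotope's positron-range kernel, flux-corrected
#' depth-to-energy conversion, and simultaneous anchor normalization.
#'
#' @param fit a \linkS4class{DecayFitResult}.
#' @param map the target's \linkS4class{EnergyDepthMap}.
#' @param material the target \linkS4class{Material}.
#' @param beam the \linkS4class{BeamSpec} of the irradiation.
#' @param kernels named list of \linkS4class{BlurKernel}.
#' @param yieldFactors named numeric vector.
#' @param anchor see \code{\link{normalizeToAnchor}}.
#' @param deconvolveIter Richardson-Lucy iterations.
#' @param removalCrossSection flux-correction knob (barn).
#' @param energyRange output band (MeV).
#' @return Named list of \linkS4class{CrossSectionTable}.
#' @export
extractCrossSections <- function(fit, map, material, beam, kernels,
                                 yieldFactors,
                                 anchor = list(isotope = "O15", energy = 35,
                                               sigma = 76.8,
                                               relUncertainty = 0.0245),
                                 deconvolveIter = 50,
                                 removalCrossSection = 0.1,
                                 energyRange = c(5, 70)) {
  res <- resolveComponentProfiles(fit)
  if (length(res$depth) != length(map@depthGrid) ||
      max(abs(res$depth - map@depthGrid)) > 1e-9)
    stop("decomposition depth grid does not match the energy-depth map; ",
         "build the map with the camera's depthExtent and pixel pitch")
  rel <- lapply(setNames(res$isotopes, res$isotopes), function(iso) {
    prof <- res$profiles[, iso]
    sig <- res$sigma[, iso]
    prof[res$mask] <- 0
    sig[res$mask] <- 0
    ## fractional uncertainties survive the (count-conserving) deblur
    frac <- ifelse(prof > 0, sig / prof, 0)
    deb <- deconvolveProfile(prof, kernels[[iso]], nIter = deconvolveIter)
    pr <- amplitudesToProduction(deb, fit@components[[iso]], beam,
                                 yieldFactors[[iso]],
                                 sigma = deb * frac)
    toEnergyAxis(pr$rate, map, material, sigma = pr$sigma,
                 mask = res$mask,
                 removalCrossSection = removalCrossSection,
                 energyRange = energyRange)
  })
  normalizeToAnchor(rel, anchor = anchor,
                    meta = list(stage = "extract"))
}
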