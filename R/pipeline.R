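## End-to-end convenience wrappers: simulate a complete experiment and run
## the full extraction chain, as used by the closed-loop test suites.

#' @useDynLib CherenkovXS, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Simulate a complete Cherenkov experiment
#'
#' Builds the configured material/beam/camera, evaluates the truth model,
#' renders the noisy frame stack and matching dark frames, and returns
#' everything needed for a closed-loop analysis together with the ground
#' truth.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param seed integer; drives all randomness of the simulation.
#' @param truth a \linkS4class{TruthXsecModel}.
#' @param noise logical; FALSE renders the noise-free expectation.
#' @return List with \code{stack}, \code{dark}, \code{map},
#'   \code{production}, \code{kernels}, \code{yieldFactors},
#'   \code{truth}, and the materialized \code{objects}.
#' @export
simulateExperiment <- function(config = defaultRunConfig(), seed = 1L,
                               truth = defaultTruthModel(config$isotopes),
                               noise = TRUE) {
  obj <- configObjects(config)
  map <- buildEnergyDepthMap(obj$material, obj$beam,
                             depthStep = obj$ccd@pixelPitch,
                             maxDepth = obj$ccd@depthExtent)
  production <- productionRateProfile(truth, map, obj$beam, obj$material,
                                      config$removalCrossSection)
  kernels <- lapply(obj$components, buildBlurKernel,
                    material = obj$material,
                    depthStep = obj$ccd@pixelPitch,
                    scaleFactor = config$kernelScaleFactor)
  yieldFactors <- vapply(obj$components, cherenkovYieldFactor,
                         0, material = obj$material)
  stack <- renderCherenkovStack(production, obj$components, obj$beam,
                                obj$ccd, kernels, yieldFactors,
                                photonScale = config$photonScale,
                                noise = noise, seed = seed)
  dark <- renderDarkFrames(obj$ccd, nFrames = 20, beam = obj$beam,
                           seed = seed + 1L)
  hash <- configHash(config)
  stack@meta$configHash <- hash
  list(stack = stack, dark = dark, map = map, production = production,
       kernels = kernels, yieldFactors = yieldFactors, truth = truth,
       objects = obj, configHash = hash)
}

#' Preprocess a raw stack to a depth-profile series
#'
#' Background subtraction, per-frame median filtering, lateral projection
#' and edge masking, with the configured parameters.
#'
#' @param stack raw \linkS4class{CherenkovStack}.
#' @param dark dark-frame \linkS4class{CherenkovStack}.
#' @param config configuration list.
#' @return A \linkS4class{DepthProfileSeries}.
#' @export
preprocessStack <- function(stack, dark, config = defaultRunConfig()) {
  stack |>
    subtractBackground(dark) |>
    medianFilterFrames(config$medianWindow) |>
    projectToDepth() |>
    applyEdgeMask(config$edgeMaskDepth)
}

#' Run the full extraction chain on a simulated experiment
#'
#' Preprocess, decompose, deblur, convert to energy and normalize; the
#' one-call closed loop.
#'
#' @param sim output of \code{\link{simulateExperiment}}.
#' @param config configuration list.
#' @return Named list of \linkS4class{CrossSectionTable}.
#' @export
runExtraction <- function(sim, config = defaultRunConfig()) {
  series <- preprocessStack(sim$stack, sim$dark, config)
  fit <- fitFixedLambda(series, sim$objects$components,
                        window = config$fitWindow)
  extractCrossSections(fit, sim$map, sim$objects$material,
                       sim$objects$beam, sim$kernels, sim$yieldFactors,
                       anchor = config$anchor,
                       deconvolveIter = config$deconvolveIter,
                       removalCrossSection = config$removalCrossSection,
                       energyRange = config$energyRange)
}
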