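## Image preprocessing: background subtraction, median filtering, lateral
## projection to depth profiles, edge masking, and time binning.

#' Subtract the dark background
#'
#' Subtracts the mean dark frame pixelwise from every frame and attaches a
#' per-pixel variance estimate: shot noise of the raw counts (gain-scaled
#' Poisson), read noise, and the uncertainty of the dark mean.  Refuses to
#' run without dark frames - there is no silent zero-background path.
#'
#' @param stack a \linkS4class{CherenkovStack} of raw frames.
#' @param darkFrames a \linkS4class{CherenkovStack} of dark frames with the
#'   same pixel geometry.
#' @return A background-corrected \linkS4class{CherenkovStack} with a
#'   variance array.
#' @export
subtractBackground <- function(stack, darkFrames) {
  if (missing(darkFrames) || is.null(darkFrames) || nFrames(darkFrames) == 0)
    stop("dark frames are required for background subtraction")
  d <- dim(stack@frames); dd <- dim(darkFrames@frames)
  if (!identical(d[1:2], dd[1:2]))
    stop("dark frames have different pixel geometry")
  darkMean <- rowMeans(darkFrames@frames, dims = 2)
  gain <- if (!is.null(stack@meta$gain)) stack@meta$gain else 1
  rn <- if (!is.null(stack@meta$readNoiseSigma)) stack@meta$readNoiseSigma else 0
  nD <- dd[3]
  ## var(dark mean) per pixel: (gain * dark + read^2)/nD, using the mean as
  ## the Poisson-level estimate
  darkVar <- (gain * pmax(darkMean, 0) + rn^2) / nD
  corrected <- sweep(stack@frames, 1:2, darkMean)
  vari <- gain * pmax(stack@frames, 0) + rn^2
  vari <- sweep(vari, 1:2, darkVar, "+")
  .cherenkovStack(corrected, stack@frameTimes, stack@exposure,
                  stack@pixelPitch, variance = vari,
                  meta = c(stack@meta[setdiff(names(stack@meta), "stage")],
                           list(stage = "background-corrected")))
}

#' Median-filter every frame
#'
#' Exact 2-D median with a square window applied to each frame
#' independently (replicated borders).  Window 1 is the identity.  The
#' variance array, if present, is carried through unchanged: for the
#' downstream lateral sums the smoothing-induced correlation between
#' neighboring pixels roughly cancels the per-pixel variance reduction of
#' the median, so the unfiltered estimate is the appropriate one for the
#' projected bins.
#'
#' @param stack a \linkS4class{CherenkovStack}.
#' @param window odd window side length (default 3).
#' @return A filtered \linkS4class{CherenkovStack}.
#' @export
medianFilterFrames <- function(stack, window = 3) {
  if (window %% 2 != 1 || window < 1)
    stop("median window must be an odd positive integer")
  d <- dim(stack@frames)
  filt <- array(.medianFilterStackCpp(as.numeric(stack@frames),
                                      d[1], d[2], d[3], as.integer(window)),
                dim = d)
  .cherenkovStack(filt, stack@frameTimes, stack@exposure, stack@pixelPitch,
                  variance = stack@variance, meta = stack@meta)
}

#' Auto-detect the lateral beam region of interest
#'
#' Centroid and FWHM of the lateral profile of the time-summed,
#' background-corrected image; the ROI is centered on the centroid with
#' half-width \code{roiFwhmFactor} times the FWHM (clipped to the frame).
#'
#' @param stack a background-corrected \linkS4class{CherenkovStack}.
#' @param roiFwhmFactor ROI half-width in units of the beam FWHM.
#' @return Integer vector of row indices.
#' @export
detectLateralRoi <- function(stack, roiFwhmFactor = 2) {
  prof <- pmax(rowSums(stack@frames, dims = 1), 0)
  if (sum(prof) == 0) stop("empty image: cannot detect beam ROI")
  y <- seq_along(prof)
  mu <- sum(y * prof) / sum(prof)
  sd <- sqrt(sum((y - mu)^2 * prof) / sum(prof))
  half <- roiFwhmFactor * 2.355 * sd
  rows <- which(y >= mu - half & y <= mu + half)
  if (!length(rows)) stop("empty ROI")
  rows
}

#' Project a stack to depth profiles
#'
#' Sums lateral pixels inside the ROI for every depth column of every
#' frame; variances are summed alongside.  The depth grid is bin centers at
#' the pixel pitch.
#'
#' @param stack a background-corrected \linkS4class{CherenkovStack}.
#' @param lateralRoi integer row indices, or NULL to auto-detect.
#' @return A \linkS4class{DepthProfileSeries}.
#' @export
projectToDepth <- function(stack, lateralRoi = NULL) {
  d <- dim(stack@frames)
  if (is.null(lateralRoi)) lateralRoi <- detectLateralRoi(stack)
  if (!length(lateralRoi)) stop("empty lateral ROI")
  if (min(lateralRoi) < 1 || max(lateralRoi) > d[1])
    stop("ROI outside the frame (rows 1..", d[1], ")")
  intens <- colSums(stack@frames[lateralRoi, , , drop = FALSE], dims = 1)
  vari <- if (length(stack@variance))
    colSums(stack@variance[lateralRoi, , , drop = FALSE], dims = 1)
  else
    matrix(NA_real_, d[2], d[3])
  depth <- (seq_len(d[2]) - 0.5) * stack@pixelPitch
  depthProfileSeries(intens, vari, depth, stack@frameTimes,
                     stack@exposure,
                     meta = c(stack@meta[setdiff(names(stack@meta), "stage")],
                              list(stage = "projected",
                                   roi = range(lateralRoi))))
}

#' Mask the shallow edge-artifact region
#'
#' The first 0.12 cm of depth shows an artificial intensity drop caused by
#' the finite target size and the camera viewing angle; bins shallower than
#' \code{minDepth} are masked and excluded from all downstream fits.
#'
#' @param series a \linkS4class{DepthProfileSeries}.
#' @param minDepth cm (default 0.12).
#' @return The series with its mask updated.
#' @export
applyEdgeMask <- function(series, minDepth = 0.12) {
  depth <- profileDepth(series)
  if (minDepth > max(depth))
    stop("minDepth (", minDepth, " cm) is beyond the imaged depth range")
  rd <- SummarizedExperiment::rowData(series)
  rd$mask <- rd$mask | depth < minDepth
  SummarizedExperiment::rowData(series) <- rd
  series
}

#' Merge frames in time bins
#'
#' Sums groups of consecutive frames (exposure-weighted by construction:
#' counts and variances add; the merged frame keeps the first start time
#' and the summed exposure).  Used to equalize SNR late in the decay.
#'
#' @param series a \linkS4class{DepthProfileSeries}.
#' @param groupSize frames per merged bin.
#' @return A merged \linkS4class{DepthProfileSeries}.
#' @export
mergeFrames <- function(series, groupSize = 5) {
  if (groupSize <= 1) return(series)
  nt <- ncol(series)
  grp <- (seq_len(nt) - 1) %/% groupSize
  keep <- grp < max(grp) | sum(grp == max(grp)) == groupSize
  grp <- grp[keep]
  agg <- function(m) {
    out <- t(rowsum(t(m[, keep, drop = FALSE]), grp))
    dimnames(out) <- NULL
    out
  }
  t1 <- frameTimes(series)[keep]
  expo <- frameExposures(series)[keep]
  depthProfileSeries(agg(intensityMatrix(series)),
                     agg(varianceMatrix(series)),
                     profileDepth(series),
                     as.numeric(tapply(t1, grp, min)),
                     as.numeric(tapply(expo, grp, sum)),
                     mask = depthMask(series),
                     meta = S4Vectors::metadata(series))
}
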