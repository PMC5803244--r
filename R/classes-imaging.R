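## Imaging containers: raw frame stacks and projected depth-profile series.

#' A timestamped Cherenkov CCD frame stack
#'
#' Frames are stored as a 3-D array \code{[lateral, depth, frame]} in raw
#' camera counts; the beam travels along the second (column) axis.  After
#' background subtraction a per-pixel variance estimate is attached.
#'
#' @slot frames numeric array [lateral, depth, frame], counts.
#' @slot variance numeric array of the same shape, or a 0-length array
#'   before background subtraction.
#' @slot pixelPitch cm per pixel.
#' @slot frameTimes frame start times, s after end of irradiation.
#' @slot exposure per-frame exposure(s), s (recycled to one per frame).
#' @slot meta provenance list (seed, config hash, stage).
#' @exportClass CherenkovStack
setClass("CherenkovStack",
  representation(
    frames = "array",
    variance = "array",
    pixelPitch = "numeric",
    frameTimes = "numeric",
    exposure = "numeric",
    meta = "list"
  )
)

setValidity("CherenkovStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "frames must be a 3-D array")
  else {
    if (d[3] != length(object@frameTimes))
      msg <- c(msg, "third dimension must match frameTimes")
    if (length(object@variance) && !identical(dim(object@variance), d))
      msg <- c(msg, "variance must match frames in shape")
  }
  if (any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

.cherenkovStack <- function(frames, frameTimes, exposure, pixelPitch,
                            variance = array(numeric(0), c(0, 0, 0)),
                            meta = list()) {
  new("CherenkovStack", frames = frames, variance = variance,
      pixelPitch = pixelPitch, frameTimes = frameTimes,
      exposure = rep_len(exposure, length(frameTimes)), meta = meta)
}

#' @describeIn renderCherenkovStack Number of frames in a stack.
#' @export
nFrames <- function(stack) dim(stack@frames)[3]

setMethod("show", "CherenkovStack", function(object) {
  d <- dim(object@frames)
  cat("CherenkovStack: ", d[1], " x ", d[2], " px x ", d[3], " frames, t = ",
      min(object@frameTimes), "..",
      max(object@frameTimes) + object@exposure[length(object@exposure)],
      " s, pixel ", object@pixelPitch * 1e4, " um",
      if (length(object@variance)) ", background-corrected" else "",
      "\n", sep = "")
})

## ---------------------------------------------------------------------------
## DepthProfileSeries
## ---------------------------------------------------------------------------

#' Depth-profile time series
#'
#' Background-corrected one-dimensional light intensity versus depth for each
#' timestamped frame, with a matching variance estimate and a mask of
#' excluded depth bins.  Extends
#' \linkS4class{SummarizedExperiment}: assays \code{intensity} and
#' \code{variance} are depth x frame matrices, \code{rowData} carries
#' \code{depth} (cm) and the logical \code{mask} (TRUE = excluded),
#' \code{colData} carries frame \code{time} and \code{exposure} (s).
#'
#' @exportClass DepthProfileSeries
setClass("DepthProfileSeries", contains = "SummarizedExperiment")

setValidity("DepthProfileSeries", function(object) {
  msg <- character()
  if (!all(c("intensity", "variance") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'intensity' and 'variance' are required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("depth", "mask") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'depth' and 'mask'")
  else if (any(diff(rd$depth) <= 0))
    msg <- c(msg, "depth grid must be strictly increasing")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("time", "exposure") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'time' and 'exposure'")
  if (length(msg)) msg else TRUE
})

#' Construct a DepthProfileSeries
#'
#' @param intensity depth x frame matrix of background-corrected counts.
#' @param variance matching variance matrix.
#' @param depth depth grid (cm, bin centers, strictly increasing).
#' @param time frame start times (s).
#' @param exposure per-frame exposures (s), recycled.
#' @param mask logical vector of excluded depth bins.
#' @param meta provenance list.
#' @return A \linkS4class{DepthProfileSeries}.
#' @export
depthProfileSeries <- function(intensity, variance, depth, time,
                               exposure = 5, mask = rep(FALSE, length(depth)),
                               meta = list()) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity, variance = variance),
    rowData = S4Vectors::DataFrame(depth = depth, mask = mask),
    colData = S4Vectors::DataFrame(time = time,
                                   exposure = rep_len(exposure, length(time))),
    metadata = meta)
  new("DepthProfileSeries", se)
}

#' Accessors for DepthProfileSeries
#'
#' @param series a \linkS4class{DepthProfileSeries}.
#' @return \code{profileDepth}: depth grid (cm); \code{frameTimes}: frame
#'   start times (s); \code{frameExposures}: exposures (s);
#'   \code{intensityMatrix}, \code{varianceMatrix}: depth x frame matrices;
#'   \code{depthMask}: logical vector of excluded bins.
#' @name series-accessors
NULL

#' @rdname series-accessors
#' @export
profileDepth <- function(series) SummarizedExperiment::rowData(series)$depth

#' @rdname series-accessors
#' @export
frameTimes <- function(series) {
  if (is(series, "CherenkovStack")) return(series@frameTimes)
  SummarizedExperiment::colData(series)$time
}

#' @rdname series-accessors
#' @export
frameExposures <- function(series) {
  if (is(series, "CherenkovStack")) return(series@exposure)
  SummarizedExperiment::colData(series)$exposure
}

#' @rdname series-accessors
#' @export
intensityMatrix <- function(series)
  SummarizedExperiment::assay(series, "intensity")

#' @rdname series-accessors
#' @export
varianceMatrix <- function(series)
  SummarizedExperiment::assay(series, "variance")

#' @rdname series-accessors
#' @export
depthMask <- function(series) SummarizedExperiment::rowData(series)$mask

setMethod("show", "DepthProfileSeries", function(object) {
  cat("DepthProfileSeries: ", nrow(object), " depth bins x ", ncol(object),
      " frames, depth ", format(min(profileDepth(object)), digits = 3), "..",
      format(max(profileDepth(object)), digits = 3), " cm, ",
      sum(depthMask(object)), " masked bins\n", sep = "")
})
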