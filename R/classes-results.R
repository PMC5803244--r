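## Result containers: decay-fit results, blur kernels, cross-section tables,
## forward-model profiles.

#' Fixed-half-life decay decomposition result
#'
#' Per-depth amplitudes of the exponential components, with their covariance
#' and a goodness-of-fit statistic.  The amplitude convention is the
#' yield-weighted number of atoms present at the amplitude reference time
#' (end of irradiation): the model for the counts in a frame starting at t
#' with exposure tau is \eqn{\sum_i a_i (e^{-\lambda_i t} -
#' e^{-\lambda_i (t+\tau)})}.
#'
#' @slot amplitudes depth x component matrix.
#' @slot sigma matching standard errors.
#' @slot covariance array [component, component, depth].
#' @slot chi2 per-depth weighted residual sum of squares.
#' @slot dof residual degrees of freedom.
#' @slot window fit window (s, s).
#' @slot components list of \linkS4class{DecayComponent}.
#' @slot depth depth grid (cm).
#' @slot mask logical, excluded depth bins.
#' @exportClass DecayFitResult
setClass("DecayFitResult",
  representation(
    amplitudes = "matrix",
    sigma = "matrix",
    covariance = "array",
    chi2 = "numeric",
    dof = "numeric",
    window = "numeric",
    components = "list",
    depth = "numeric",
    mask = "logical"
  )
)

setValidity("DecayFitResult", function(object) {
  msg <- character()
  k <- length(object@components)
  if (ncol(object@amplitudes) != k)
    msg <- c(msg, "amplitude columns must match components")
  if (!identical(dim(object@amplitudes), dim(object@sigma)))
    msg <- c(msg, "sigma must match amplitudes in shape")
  if (nrow(object@amplitudes) != length(object@depth))
    msg <- c(msg, "amplitude rows must match depth grid")
  ok <- !object@mask
  if (any(!is.finite(object@amplitudes[ok, ])))
    msg <- c(msg, "amplitudes must be finite on unmasked bins")
  for (i in which(ok)) {
    C <- object@covariance[, , i]
    if (max(abs(C - t(C))) > 1e-8 * (max(abs(C)) + 1e-300)) {
      msg <- c(msg, "covariance must be symmetric")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn fitFixedLambda Amplitude matrix accessor (depth x component).
#' @export
amplitudes <- function(fit) fit@amplitudes

#' @describeIn fitFixedLambda Amplitude standard-error accessor.
#' @export
amplitudeSigma <- function(fit) fit@sigma

setMethod("show", "DecayFitResult", function(object) {
  cat("DecayFitResult: ", nrow(object@amplitudes), " depth bins x ",
      ncol(object@amplitudes), " components (",
      paste(vapply(object@components, isotope, ""), collapse = ", "),
      "), window ", object@window[1], "-", object@window[2], " s\n", sep = "")
})

## ---------------------------------------------------------------------------
## BlurKernel
## ---------------------------------------------------------------------------

#' Positron-range Cherenkov blur kernel
#'
#' A symmetric, unit-area, one-dimensional kernel on the depth grid.
#'
#' @slot isotope isotope label.
#' @slot scale characteristic length (cm); for the Laplacian family the
#'   e-folding length of \eqn{\exp(-|z|/L)}.
#' @slot step grid step (cm).
#' @slot weights odd-length numeric vector summing to 1.
#' @exportClass BlurKernel
setClass("BlurKernel",
  representation(
    isotope = "character",
    scale = "numeric",
    step = "numeric",
    weights = "numeric"
  )
)

setValidity("BlurKernel", function(object) {
  msg <- character()
  w <- object@weights
  if (length(w) %% 2 != 1) msg <- c(msg, "kernel length must be odd")
  if (any(w < 0)) msg <- c(msg, "kernel must be nonnegative")
  if (abs(sum(w) - 1) > 1e-12) msg <- c(msg, "kernel must sum to 1")
  if (max(abs(w - rev(w))) > 1e-12) msg <- c(msg, "kernel must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn buildBlurKernel Kernel weights accessor.
#' @export
kernelWeights <- function(kernel) kernel@weights

setMethod("show", "BlurKernel", function(object) {
  cat("BlurKernel ", object@isotope, ": L = ",
      format(object@scale, digits = 3), " cm, ", length(object@weights),
      " taps at ", object@step * 1e4, " um\n", sep = "")
})

## ---------------------------------------------------------------------------
## CrossSectionTable
## ---------------------------------------------------------------------------

#' Per-isotope cross-section table
#'
#' Rows of (energy, energy uncertainty, sigma, sigma uncertainty) on a
#' strictly increasing energy grid, in MeV and mbarn, plus provenance
#' metadata (anchor used, config hash, stage).
#'
#' @slot isotope isotope label.
#' @slot table data.frame with columns energy, denergy, sigma, dsigma.
#' @slot meta provenance list.
#' @exportClass CrossSectionTable
setClass("CrossSectionTable",
  representation(
    isotope = "character",
    table = "data.frame",
    meta = "list"
  )
)

setValidity("CrossSectionTable", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("energy", "denergy", "sigma", "dsigma")
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, paste("table must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (nrow(tb) == 0) msg <- c(msg, "table must not be empty")
    if (any(diff(tb$energy) <= 0))
      msg <- c(msg, "energies must be strictly increasing")
    if (any(tb$sigma < 0)) msg <- c(msg, "sigma must be nonnegative")
    if (any(tb$dsigma < 0) || any(tb$denergy < 0))
      msg <- c(msg, "uncertainties must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CrossSectionTable
#'
#' @param isotope isotope label.
#' @param energy MeV, strictly increasing.
#' @param sigma mbarn.
#' @param denergy energy uncertainties (MeV).
#' @param dsigma cross-section uncertainties (mbarn).
#' @param meta provenance list.
#' @return A \linkS4class{CrossSectionTable}.
#' @examples
#' crossSectionTable("O15", energy = c(20, 35, 50), sigma = c(40, 76.8, 60))
#' @export
crossSectionTable <- function(isotope, energy, sigma,
                              denergy = rep(0, length(energy)),
                              dsigma = rep(0, length(energy)),
                              meta = list()) {
  new("CrossSectionTable", isotope = isotope,
      table = data.frame(energy = energy, denergy = denergy,
                         sigma = sigma, dsigma = dsigma),
      meta = meta)
}

#' @describeIn crossSectionTable Underlying data.frame accessor.
#' @param x a \linkS4class{CrossSectionTable}.
#' @export
xsTable <- function(x) x@table

#' Interpolate a cross-section table
#'
#' Linear interpolation in energy; 0 outside the tabulated range below, and
#' an error above (missing coverage must be explicit, not extrapolated).
#'
#' @param x a \linkS4class{CrossSectionTable}.
#' @param energy MeV (vectorized).
#' @param what "sigma" or "dsigma".
#' @return mbarn.
#' @export
xsAt <- function(x, energy, what = c("sigma", "dsigma")) {
  what <- match.arg(what)
  tb <- x@table
  if (any(energy > max(tb$energy) + 1e-9))
    stop("cross-section table for ", x@isotope, " covers only up to ",
         max(tb$energy), " MeV; requested up to ", max(energy), " MeV")
  approx(tb$energy, tb[[what]], xout = energy, rule = 1)$y |>
    (\(v) ifelse(is.na(v), 0, v))()
}

setMethod("show", "CrossSectionTable", function(object) {
  tb <- object@table
  cat("CrossSectionTable ", object@isotope, ": ", nrow(tb), " points, ",
      format(min(tb$energy), digits = 3), "-",
      format(max(tb$energy), digits = 3), " MeV, max sigma ",
      format(max(tb$sigma), digits = 4), " mbarn\n", sep = "")
})

## ---------------------------------------------------------------------------
## ForwardProfile
## ---------------------------------------------------------------------------

#' Time-windowed positron depth profile
#'
#' Positrons emitted per incident proton per depth bin inside a time window,
#' before and after PSF smearing.
#'
#' @slot depth depth grid (cm).
#' @slot window (t1, t2) in s after end of irradiation.
#' @slot raw positrons per incident proton per bin, unsmeared.
#' @slot smeared PSF-smeared variant (total conserved).
#' @slot sigma per-bin uncertainty of the smeared profile.
#' @slot perIsotope matrix depth x isotope of the unsmeared summands.
#' @exportClass ForwardProfile
setClass("ForwardProfile",
  representation(
    depth = "numeric",
    window = "numeric",
    raw = "numeric",
    smeared = "numeric",
    sigma = "numeric",
    perIsotope = "matrix"
  )
)

setValidity("ForwardProfile", function(object) {
  msg <- character()
  if (any(object@raw < -1e-12)) msg <- c(msg, "profile must be nonnegative")
  if (length(object@smeared) &&
      abs(sum(object@smeared) - sum(object@raw)) >
        1e-6 * (sum(object@raw) + 1e-300))
    msg <- c(msg, "PSF smearing must conserve the total")
  if (length(object@window) != 2 || diff(object@window) < 0)
    msg <- c(msg, "window must be (t1, t2) with t2 >= t1")
  if (length(msg)) msg else TRUE
})

#' @describeIn forwardPositronProfile Smeared profile accessor.
#' @export
smearedProfile <- function(profile) profile@smeared

#' @describeIn forwardPositronProfile Unsmeared profile accessor.
#' @export
rawProfile <- function(profile) profile@raw

setMethod("show", "ForwardProfile", function(object) {
  cat("ForwardProfile: window ", object@window[1] / 60, "-",
      object@window[2] / 60, " min, ", length(object@depth),
      " bins, total ", format(sum(object@raw), digits = 4),
      " positrons/proton\n", sep = "")
})
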