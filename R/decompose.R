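## Fixed-half-life multi-exponential decomposition of depth-resolved light
## curves, and a free-half-life validation fit.

## Design matrix: one column per component, rows = frames; entry is the
## fraction of the t = 0 population decaying inside the frame,
## e^{-lambda t1} - e^{-lambda t2}.  Exact for any exposure length.
.decayDesign <- function(components, t1, exposure) {
  t2 <- t1 + exposure
  X <- vapply(components, .windowDecayFraction, numeric(length(t1)),
              t1 = t1, t2 = t2)
  dimnames(X) <- list(NULL, vapply(components, isotope, ""))
  X
}

#' Fit fixed-half-life exponential components at every depth
#'
#' Weighted linear least squares of the light curve at each unmasked depth
#' bin on the exposure-integrated decay basis of the given components, over
#' a fit window (default 120-3600 s: the first 120 s are discarded to let
#' the fast silicon-induced emitters and 14O die away).  Weights are
#' 1/variance.  With the half-lives fixed the problem is linear, so the
#' solution, its covariance \eqn{(X^T W X)^{-1}} and the per-depth
#' chi-squared are exact.
#'
#' An optional nonnegativity constraint solves the small
#' best-feasible-subset problem exactly (the component count is 3, so all
#' sign patterns are enumerated); low-SNR deep bins otherwise can go
#' negative.
#'
#' @param series a \linkS4class{DepthProfileSeries}.
#' @param components named list of \linkS4class{DecayComponent}; half-lives
#'   must be distinct.
#' @param window fit window (s, s) relative to end of irradiation.
#' @param nonnegative logical.
#' @return A \linkS4class{DecayFitResult}.  Amplitudes are yield-weighted
#'   atoms at the end of irradiation (see
#'   \linkS4class{DecayFitResult}).
#' @export
fitFixedLambda <- function(series, components = decayComponents(),
                           window = c(120, 3600), nonnegative = FALSE) {
  t1 <- frameTimes(series)
  expo <- frameExposures(series)
  use <- t1 >= window[1] & (t1 + expo) <= window[2]
  k <- length(components)
  if (sum(use) < 3 * k)
    stop("need at least ", 3 * k, " frames in the fit window, have ",
         sum(use))
  lam <- vapply(components, decayConstant, 0)
  if (any(duplicated(signif(lam, 12)))) {
    dup <- names(lam)[duplicated(signif(lam, 12)) |
                        duplicated(signif(lam, 12), fromLast = TRUE)]
    stop("singular design: identical decay constants for ",
         paste(dup, collapse = ", "))
  }
  X <- .decayDesign(components, t1[use], expo[use])
  Y <- intensityMatrix(series)[, use, drop = FALSE]
  V <- varianceMatrix(series)[, use, drop = FALSE]
  mask <- depthMask(series)
  nz <- nrow(Y)
  amp <- matrix(NA_real_, nz, k, dimnames = list(NULL, colnames(X)))
  sig <- amp
  covar <- array(NA_real_, c(k, k, nz))
  chi2 <- rep(NA_real_, nz)
  for (i in which(!mask)) {
    w <- 1 / V[i, ]
    if (any(!is.finite(w))) w <- rep(1, ncol(Y))
    sw <- sqrt(w)
    Xw <- X * sw
    yw <- Y[i, ] * sw
    XtX <- crossprod(Xw)
    Ci <- tryCatch(solve(XtX), error = function(e)
      stop("singular design matrix at depth bin ", i))
    a <- as.numeric(Ci %*% crossprod(Xw, yw))
    if (nonnegative && any(a < 0))
      a <- .nnlsEnumerate(Xw, yw, XtX)
    r <- yw - Xw %*% a
    amp[i, ] <- a
    covar[, , i] <- Ci
    sig[i, ] <- sqrt(diag(Ci))
    chi2[i] <- sum(r^2)
  }
  new("DecayFitResult", amplitudes = amp, sigma = sig, covariance = covar,
      chi2 = chi2, dof = sum(use) - k, window = window,
      components = components, depth = profileDepth(series), mask = mask)
}

## Exact small-k nonnegative least squares by subset enumeration.
.nnlsEnumerate <- function(Xw, yw, XtX) {
  k <- ncol(Xw)
  best <- rep(0, k); bestSse <- sum(yw^2)
  for (m in seq_len(2^k - 1)) {
    S <- which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0)
    a <- tryCatch(solve(XtX[S, S, drop = FALSE],
                        crossprod(Xw[, S, drop = FALSE], yw)),
                  error = function(e) NULL)
    if (is.null(a) || any(a < 0)) next
    sse <- sum((yw - Xw[, S, drop = FALSE] %*% a)^2)
    if (sse < bestSse) {
      bestSse <- sse
      best <- rep(0, k); best[S] <- a
    }
  }
  best
}

#' Free-half-life exponential fit of a single light curve
#'
#' Nonlinear least squares with the half-lives free, used to validate that
#' data synthesized (or measured) on the frame cadence actually encode the
#' library half-lives; the production pipeline keeps them fixed.  Solved by
#' variable projection: for trial half-lives the amplitudes are the linear
#' LSQ solution, and the half-lives are optimized with the
#' Levenberg-Marquardt algorithm.
#'
#' @param time frame start times, s.
#' @param counts frame counts.
#' @param exposure per-frame exposure, s.
#' @param nComponents 1, 2 or 3.
#' @param init initial half-lives (s); required length \code{nComponents}.
#' @param weights optional LSQ weights.
#' @return List with \code{halfLives} (sorted increasing),
#'   \code{amplitudes}, \code{converged}, and \code{identifiable} (FALSE
#'   for any component whose fitted amplitude is consistent with zero, in
#'   which case its half-life is not determined by the data).
#' @export
fitFreeHalflife <- function(time, counts, exposure = 5, nComponents = 1,
                            init = NULL, weights = NULL) {
  stopifnot(nComponents %in% 1:3)
  if (is.null(init))
    init <- c(122.2, 597.9, 1222)[seq_len(nComponents)]
  if (length(init) != nComponents)
    stop("init must supply one half-life per component")
  if (is.null(weights)) weights <- rep(1, length(time))
  expo <- rep_len(exposure, length(time))
  sw <- sqrt(weights)

  design <- function(hl) {
    lam <- log(2) / hl
    vapply(lam, function(l) exp(-l * time) - exp(-l * (time + expo)),
           numeric(length(time)))
  }
  linampl <- function(hl) {
    X <- design(hl) * sw
    qr.coef(qr(X), counts * sw)
  }
  resid <- function(loghl) {
    hl <- exp(loghl)
    X <- design(hl) * sw
    a <- qr.coef(qr(X), counts * sw)
    counts * sw - X %*% a
  }
  fit <- minpack.lm::nls.lm(par = log(init), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("free-half-life fit did not converge: ", fit$message)
  hl <- exp(fit$par)
  a <- as.numeric(linampl(hl))
  o <- order(hl)
  hl <- hl[o]; a <- a[o]
  ## identifiability: an amplitude indistinguishable from zero leaves its
  ## half-life unconstrained
  scale <- max(abs(a), 1e-300)
  identifiable <- abs(a) > 1e-6 * scale
  list(halfLives = hl, amplitudes = a, converged = converged,
       identifiable = identifiable)
}

#' Resolve per-isotope depth profiles from a decomposition
#'
#' Reshapes the fitted amplitudes into one depth profile per isotope with
#' per-bin standard errors from the fit covariance; masked bins propagate
#' as NA.
#'
#' @param fit a \linkS4class{DecayFitResult}.
#' @return List with \code{depth}, \code{mask}, and per-isotope
#'   \code{profiles} / \code{sigma} matrices (depth x isotope).
#' @export
resolveComponentProfiles <- function(fit) {
  list(depth = fit@depth, mask = fit@mask,
       profiles = fit@amplitudes, sigma = fit@sigma,
       isotopes = colnames(fit@amplitudes))
}

#' Evaluate the fitted model light curve at one depth
#'
#' @param fit a \linkS4class{DecayFitResult}.
#' @param depthIndex row index.
#' @param time frame start times (s).
#' @param exposure exposure (s).
#' @return Modeled counts per frame.
#' @export
fittedLightCurve <- function(fit, depthIndex, time, exposure = 5) {
  X <- .decayDesign(fit@components, time, rep_len(exposure, length(time)))
  as.numeric(X %*% fit@amplitudes[depthIndex, ])
}
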