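# Preprocessing: background subtraction, median filtering, projection,
# edge masking and frame merging.

makeStack <- function(arr, times = seq_len(dim(arr)[3]), exposure = 5,
                      meta = list(gain = 1, readNoiseSigma = 0,
                                  darkLevel = 0)) {
  CherenkovXS:::.cherenkovStack(arr, times, exposure, 0.0133, meta = meta)
}

test_that("background subtraction is exact on the dark mean and refuses
           to run without darks", {
  dark <- makeStack(array(100, c(8, 10, 6)))
  stack <- makeStack(array(100, c(8, 10, 3)))
  out <- subtractBackground(stack, dark)
  expect_true(all(out@frames == 0))
  expect_identical(dim(out@variance), dim(out@frames))
  # subtract-then-re-add is the identity
  sig <- array(runif(8 * 10 * 3, 50, 150), c(8, 10, 3))
  out2 <- subtractBackground(makeStack(sig), dark)
  expect_equal(out2@frames + 100, sig, tolerance = 1e-12)
  expect_error(subtractBackground(stack, NULL), "dark frames")
  expect_error(subtractBackground(stack, makeStack(array(0, c(4, 4, 2)))),
               "geometry")
})

test_that("background-corrected synthetic stack recovers the signal mean", {
  cfg <- smallConfig(exposure = 60)
  sim <- simulateExperiment(cfg, seed = 11)
  sim0 <- simulateExperiment(cfg, seed = 11, noise = FALSE)
  corr <- subtractBackground(sim$stack, sim$dark)
  sig0 <- sim0$stack@frames - cfg$ccd$darkLevel
  # mean over the whole stack within a few counting sigma
  expect_lt(abs(mean(corr@frames) - mean(sig0)),
            4 * sqrt(mean(sim0$stack@frames)) / sqrt(length(sig0)) * 10)
})

test_that("median filter removes hot pixels, keeps constants, window 1 is
           identity, even windows are refused", {
  flat <- array(7, c(15, 15, 2))
  hot <- flat; hot[8, 8, 1] <- 5000
  filt <- medianFilterFrames(makeStack(hot), 3)
  expect_equal(filt@frames, flat, tolerance = 1e-12)
  expect_identical(medianFilterFrames(makeStack(hot), 1)@frames, hot)
  expect_error(medianFilterFrames(makeStack(hot), 4), "odd")
  # exact against an apply() median oracle on random data
  set.seed(42)
  a <- array(rnorm(12 * 9 * 3), c(12, 9, 3))
  filt2 <- medianFilterFrames(makeStack(a), 3)@frames
  pad <- a[c(1, 1:12, 12), c(1, 1:9, 9), , drop = FALSE]
  for (k in 1:3) for (i in 1:12) for (j in 1:9)
    expect_identical(filt2[i, j, k],
                     median(pad[i:(i + 2), j:(j + 2), k]))
})

test_that("projection sums the ROI, is linear, and refuses bad ROIs", {
  a <- array(3, c(10, 12, 4))
  stack <- makeStack(a)
  stack@variance <- a
  s <- projectToDepth(stack, lateralRoi = 2:6)
  expect_true(all(intensityMatrix(s) == 15))
  expect_true(all(varianceMatrix(s) == 15))
  expect_equal(profileDepth(s), (seq_len(12) - 0.5) * 0.0133)
  # linearity
  b <- array(runif(10 * 12 * 4), c(10, 12, 4))
  sb <- projectToDepth(makeStack(b), lateralRoi = 2:6)
  sab <- projectToDepth(makeStack(a + b), lateralRoi = 2:6)
  expect_equal(intensityMatrix(sab),
               intensityMatrix(s) + intensityMatrix(sb), tolerance = 1e-12)
  expect_error(projectToDepth(stack, lateralRoi = integer(0)), "ROI")
  expect_error(projectToDepth(stack, lateralRoi = 5:30), "outside")
})

test_that("projection matches the generator's pre-noise profile within 3
           sigma per bin", {
  cfg <- smallConfig(exposure = 60)
  sim <- simulateExperiment(cfg, seed = 12)
  sim0 <- simulateExperiment(cfg, seed = 12, noise = FALSE)
  roi <- seq_len(dim(sim$stack@frames)[1])  # full frame: coverage exactly 1
  s <- projectToDepth(subtractBackground(sim$stack, sim$dark), roi)
  s0 <- projectToDepth(subtractBackground(sim0$stack, sim$dark), roi)
  z <- (intensityMatrix(s) - intensityMatrix(s0)) /
    sqrt(varianceMatrix(s))
  expect_gt(mean(abs(z) <= 3), 0.99)
})

test_that("edge mask hides shallow bins and conserves the bin count", {
  m <- matrix(1, 40, 6)
  s <- seriesFromMatrix(m, m, time = seq(120, 145, 5))
  s0 <- applyEdgeMask(s, 0)
  expect_identical(sum(depthMask(s0)), 0L)
  s1 <- applyEdgeMask(s)
  # bins with center shallower than 0.12 cm: centers at (i - 0.5) * 133 um
  expect_identical(which(depthMask(s1)), which(profileDepth(s) < 0.12))
  expect_identical(length(depthMask(s1)), 40L)
  expect_error(applyEdgeMask(s, 10), "beyond")
  # masked bins are excluded from fits downstream
  fit <- fitFixedLambda(s1, decayComponents("O15"), window = c(120, 150))
  expect_true(all(is.na(amplitudes(fit)[depthMask(s1), ])))
  expect_true(all(is.finite(amplitudes(fit)[!depthMask(s1), ])))
})

test_that("frame merging sums counts, variances and exposures", {
  m <- matrix(rep(1:10, each = 5), 5, 10)
  v <- m * 2
  s <- seriesFromMatrix(m, v, time = seq(120, 165, 5))
  sm <- mergeFrames(s, 5)
  expect_identical(ncol(sm), 2L)
  expect_equal(intensityMatrix(sm)[1, ], c(sum(1:5), sum(6:10)))
  expect_equal(varianceMatrix(sm)[1, ], 2 * c(sum(1:5), sum(6:10)))
  expect_equal(frameExposures(sm), c(25, 25))
  expect_equal(frameTimes(sm), c(120, 145))
})
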