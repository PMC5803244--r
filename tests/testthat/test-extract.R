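# Cross-section extraction: build-up inversion, energy-axis mapping,
# anchor normalization and the noise-free closed loop.

test_that("build-up inversion has the stated saturation behavior", {
  comps <- decayComponents(c("O15", "C11"))
  beam <- beamSpec(72, 30, 1800)
  a <- c(10, 20, 30)
  # saturation limit: R -> a * lambda / yield as t_irr -> infinity
  beamInf <- beamSpec(72, 30, 1e9)
  r <- amplitudesToProduction(a, comps$O15, beamInf, yieldFactor = 2)
  expect_equal(r$rate, a * decayConstant(comps$O15) / 2, tolerance = 1e-9)
  # equal amplitudes, faster decay -> more production
  rO <- amplitudesToProduction(1, comps$O15, beam, 1)$rate
  rC <- amplitudesToProduction(1, comps$C11, beam, 1)$rate
  expect_gt(rO, rC)
  # tiny lambda * t_irr stays finite and correct (series limit R = a/tIrr)
  slow <- decayComponents("C11")$C11
  slow@halfLife <- 1e9; slow@decayConstant <- log(2) / 1e9
  r2 <- amplitudesToProduction(100, slow, beamSpec(72, 1, 10), 1)
  expect_equal(r2$rate, 100 / 10, tolerance = 1e-6)
  # uncertainties scale identically
  r3 <- amplitudesToProduction(a, comps$O15, beam, 2, sigma = a / 10)
  expect_equal(r3$sigma / r3$rate, rep(0.1, 3), tolerance = 1e-12)
})

test_that("noise-free closed loop recovers the generator production
           within 2%", {
  cfg <- smallConfig()
  cfg$kernelScaleFactor <- 0  # delta kernels isolate the inversion
  sim <- simulateExperiment(cfg, seed = 1, noise = FALSE)
  # noise off includes the dark reference: an exact dark mean
  exactDark <- CherenkovXS:::.cherenkovStack(
    array(cfg$ccd$darkLevel, dim(sim$stack@frames)),
    frameTimes(sim$stack), cfg$ccd$exposure, cfg$ccd$pixelPitch,
    meta = sim$dark@meta)
  corr <- subtractBackground(sim$stack, exactDark)
  corr@variance <- corr@variance * 0 + 1
  s <- projectToDepth(corr, seq_len(dim(corr@frames)[1]))
  fit <- fitFixedLambda(s, sim$objects$components)
  for (iso in sim$production$isotopes) {
    rec <- amplitudesToProduction(amplitudes(fit)[, iso],
                                  sim$objects$components[[iso]],
                                  sim$objects$beam,
                                  sim$yieldFactors[[iso]])$rate /
      cfg$photonScale
    truth <- sim$production$rate[, iso]
    big <- truth > 0.05 * max(truth)
    expect_lt(max(abs(rec[big] / truth[big] - 1)), 0.02)
  }
})

test_that("energy-axis mapping: flat production gives flat sigma, flux
           correction raises deep-bin sigma", {
  w <- standardMaterial("water")
  map <- buildEnergyDepthMap(w, beamSpec(69.2, 5, 5))
  n <- length(map@depthGrid)
  flat <- rep(1, n)
  suppressMessages({
    tb <- toEnergyAxis(flat, map, w, removalCrossSection = NULL)
    tbf <- toEnergyAxis(flat, map, w, removalCrossSection = 0.1)
  })
  expect_lt(diff(range(tb$sigma)) / mean(tb$sigma), 1e-9)
  # disabling the correction scales deep bins (low E) down
  deep <- tbf$energy < 20
  expect_true(all(tbf$sigma[deep] > tb$sigma[deep]))
  # energies strictly increasing, restricted to 5-70 MeV
  expect_true(all(diff(tb$energy) > 0))
  expect_true(all(tb$energy >= 5 & tb$energy <= 70))
  # energy uncertainties grow toward low energy (straggling)
  expect_true(all(diff(tb$denergy) < 0))
  # bins past the Bragg peak are dropped with a message
  mapLong <- buildEnergyDepthMap(w, beamSpec(69.2, 5, 5),
                                 maxDepth = csdaRange(map) + 0.3)
  expect_message(toEnergyAxis(rep(1, length(mapLong@depthGrid)), mapLong, w),
                 "past the proton range")
})

test_that("anchor normalization pins the 15O maximum and preserves
           ratios", {
  E <- seq(5, 70, by = 0.5)
  tm <- defaultTruthModel()
  rel <- lapply(setNames(names(tm@params), names(tm@params)), function(iso)
    data.frame(energy = E, denergy = 0.5,
               sigma = truthSigma(tm, iso, E) * 0.0123,  # arbitrary scale
               dsigma = truthSigma(tm, iso, E) * 0.0123 * 0.01))
  tabs <- normalizeToAnchor(rel)
  pk <- CherenkovXS:::.quadraticPeak(xsTable(tabs$O15)$energy,
                                     xsTable(tabs$O15)$sigma)
  expect_equal(pk$y, 76.8, tolerance = 1e-9)
  expect_equal(pk$x, 35, tolerance = 0.1)
  # same factor for every isotope: ratios unchanged
  i <- 60
  expect_equal(xsTable(tabs$N13)$sigma[i] / xsTable(tabs$O15)$sigma[i],
               rel$N13$sigma[i] / rel$O15$sigma[i], tolerance = 1e-12)
  # anchor uncertainty is a quadrature floor on every point
  for (tb in tabs) {
    t <- xsTable(tb)
    nz <- t$sigma > 0
    expect_true(all(t$dsigma[nz] / t$sigma[nz] >= 0.0245 - 1e-12))
  }
  # degenerate anchors are refused
  rel0 <- rel
  rel0$O15$sigma <- 0
  expect_error(normalizeToAnchor(rel0), "empty or all zero")
  expect_error(normalizeToAnchor(rel["N13"]), "not among")
  # an anchor far from the relative maximum warns
  expect_warning(
    normalizeToAnchor(rel, anchor = list(isotope = "O15", energy = 45,
                                         sigma = 76.8,
                                         relUncertainty = 0.0245)),
    "more than 2 MeV")
})

test_that("full noise-free extraction tracks the truth within 3% RMS over
           20-65 MeV", {
  cfg <- smallConfig()
  sim <- simulateExperiment(cfg, seed = 1, noise = FALSE)
  suppressMessages(tabs <- runExtraction(sim, cfg))
  for (iso in names(tabs)) {
    tb <- xsTable(tabs[[iso]])
    sel <- tb$energy >= 20 & tb$energy <= 65
    tr <- truthSigma(sim$truth, iso, tb$energy[sel])
    keep <- tr >= 0.1 * max(truthSigma(sim$truth, iso, seq(5, 70, 0.1)))
    rms <- sqrt(mean(((tb$sigma[sel][keep] - tr[keep]) / tr[keep])^2))
    expect_lt(rms, 0.03)
  }
})

test_that("straggling-matched rebinning keeps the curve and shrinks the
           point count", {
  E <- seq(5, 70, by = 0.25)
  tb <- crossSectionTable("O15", E, truthSigma(defaultTruthModel(), "O15", E),
                          denergy = rep(1.5, length(E)),
                          dsigma = rep(1, length(E)))
  rb <- rebinToStraggling(tb)
  expect_lt(nrow(xsTable(rb)), nrow(xsTable(tb)))
  # rebinned values interpolate the original curve
  o <- approx(E, xsTable(tb)$sigma, xout = xsTable(rb)$energy)$y
  expect_equal(xsTable(rb)$sigma, o, tolerance = 0.05)
})
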