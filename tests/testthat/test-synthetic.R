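# Synthetic generator: truth curves, production profiles, activation
# kinetics against an ODE oracle, stack rendering properties and seeded
# reproducibility.

test_that("truth curves respect thresholds and qualitative ordering", {
  tm <- defaultTruthModel()
  E <- seq(1, 70, by = 0.1)
  for (iso in c("O15", "N13", "C11")) {
    s <- truthSigma(tm, iso, E)
    expect_true(all(s >= 0))
    expect_true(all(s[E <= truthThreshold(tm, iso)] == 0))
  }
  # threshold ordering: N13 (p,alpha) < O15 (p,pn) < C11
  expect_lt(truthThreshold(tm, "N13"), truthThreshold(tm, "O15"))
  expect_lt(truthThreshold(tm, "O15"), truthThreshold(tm, "C11"))
  # 15O peaks at 35 MeV at the anchor value
  pkE <- optimize(function(e) -truthSigma(tm, "O15", e), c(20, 60))$minimum
  expect_equal(pkE, 35, tolerance = 1e-3)
  expect_equal(truthSigma(tm, "O15", 35), 76.8, tolerance = 1e-9)
  # 13N resonance structure lives at 10-20 MeV; 11C rises over 30-45
  expect_gt(max(truthSigma(tm, "N13", seq(10, 20, 0.1))),
            max(truthSigma(tm, "N13", seq(25, 70, 0.1))))
  expect_gt(truthSigma(tm, "C11", 45), 2 * truthSigma(tm, "C11", 32))
})

test_that("production profile is sigma(E(z)) Phi(z) n_O dz with cutoffs", {
  obj <- quartzObjects()
  map <- buildEnergyDepthMap(obj$material, obj$beam,
                             depthStep = obj$ccd@pixelPitch,
                             maxDepth = obj$ccd@depthExtent)
  tm <- defaultTruthModel()
  pr <- productionRateProfile(tm, map, obj$beam, obj$material)
  inRange <- map@energyAtDepth > 0
  expect_true(all(pr$rate[!inRange, ] == 0))
  # zero below threshold
  below <- inRange & map@energyAtDepth < truthThreshold(tm, "C11")
  expect_true(all(pr$rate[below, "C11"] == 0))
  # linear in beam current
  beam2 <- beamSpec(72, 60, 1800)
  pr2 <- productionRateProfile(tm, map, beam2, obj$material)
  expect_equal(pr2$rate, 2 * pr$rate, tolerance = 1e-12)
  # direct value at one depth
  i <- which(inRange)[50]
  expected <- protonRate(obj$beam) *
    fluxAttenuation(obj$material, pr$depth[i]) *
    numberDensity(obj$material, "O") *
    truthSigma(tm, "O15", map@energyAtDepth[i]) * 1e-27 * 0.0133
  expect_equal(unname(pr$rate[i, "O15"]), expected, tolerance = 1e-12)
  # material mismatch refused
  expect_error(productionRateProfile(tm, map, obj$beam,
                                     standardMaterial("water")),
               "built for material")
})

test_that("activation closed form matches ODE integration to 1e-8", {
  comp <- decayComponents("O15")$O15
  R <- 1234; tIrr <- 1800
  lam <- decayConstant(comp)
  ode <- deSolve::lsoda(c(N = 0), seq(0, tIrr, length.out = 5),
                        function(t, y, p) list(R - lam * y),
                        rtol = 1e-12, atol = 1e-8)
  Nend <- unname(ode[nrow(ode), "N"])
  for (t in c(0, 61.1, 122.2, 1000)) {
    expect_equal(activityAfterIrradiation(R, comp, tIrr, t),
                 lam * Nend * exp(-lam * t), tolerance = 1e-8)
  }
  # saturation limit and half-life definition
  expect_equal(activityAfterIrradiation(R, comp, 1e9, 0), R,
               tolerance = 1e-12)
  a0 <- activityAfterIrradiation(R, comp, tIrr, 0)
  expect_equal(activityAfterIrradiation(R, comp, tIrr, halfLife(comp)),
               a0 / 2, tolerance = 1e-12)
  expect_error(activityAfterIrradiation(R, comp, tIrr, -5), "nonnegative")
})

test_that("decay components encode lambda * T1/2 = ln 2 and the library", {
  comps <- decayComponents(c("O15", "N13", "C11", "O14"))
  expect_equal(vapply(comps, halfLife, 0),
               c(O15 = 122.2, N13 = 597.9, C11 = 1222, O14 = 70.62))
  for (c in comps)
    expect_equal(decayConstant(c) * halfLife(c), log(2), tolerance = 1e-14)
  expect_error(decayComponents("F18"), "unknown isotope")
})

test_that("rendering is seed-reproducible and additive in signal", {
  cfg <- smallConfig(exposure = 60)
  sim1 <- simulateExperiment(cfg, seed = 7)
  sim2 <- simulateExperiment(cfg, seed = 7)
  expect_identical(sim1$stack@frames, sim2$stack@frames)
  sim3 <- simulateExperiment(cfg, seed = 8)
  expect_false(identical(sim1$stack@frames, sim3$stack@frames))
  # zero activity renders pure dark + noise
  tm0 <- defaultTruthModel()
  for (iso in names(tm0@params)) {
    tm0@params[[iso]]$peakValue <- 0
    tm0@params[[iso]]$bumps <- matrix(numeric(0), 0, 3)
  }
  sim0 <- simulateExperiment(cfg, seed = 7, truth = tm0, noise = FALSE)
  expect_true(all(abs(sim0$stack@frames - cfg$ccd$darkLevel) < 1e-9))
  # frame windows before t = 0 are refused at construction
  expect_error(ccdConfig(frameTimes = c(-10, 0, 10), depthExtent = 1,
                         lateralExtent = 0.2),
               "nonnegative")
})

test_that("noise-free render equals kernel shape for a delta source", {
  obj <- quartzObjects()
  comps <- decayComponents("O15")
  ccd <- ccdConfig(exposure = 5, frameTimes = c(120, 125),
                   depthExtent = 0.7, lateralExtent = 0.2,
                   darkLevel = 0, readNoiseSigma = 0)
  nz <- round(ccd@depthExtent / ccd@pixelPitch)
  rate <- matrix(0, nz, 1, dimnames = list(NULL, "O15"))
  rate[25, 1] <- 1e6
  prod <- list(depth = (seq_len(nz) - 0.5) * ccd@pixelPitch, rate = rate,
               isotopes = "O15")
  kern <- buildBlurKernel(comps$O15, obj$material, ccd@pixelPitch)
  stack <- renderCherenkovStack(prod, comps, obj$beam, ccd,
                                list(O15 = kern), c(O15 = 1),
                                photonScale = 1, noise = FALSE)
  profile <- colSums(stack@frames[, , 1])
  lam <- decayConstant(comps$O15)
  n0 <- 1e6 * (-expm1(-lam * 1800)) / lam
  expected <- convolveProfile(replace(numeric(nz), 25, n0), kern) *
    (exp(-lam * 120) - exp(-lam * 125))
  expect_equal(profile, expected, tolerance = 1e-9)
})

test_that("late-window total light decays at the 11C rate", {
  # by ~9000 s the 13N contribution is down to ~1% of the count rate, so a
  # free single-exponential fit over 9000-10800 s must recover the 11C
  # half-life to within 2%
  cfg <- smallConfig()
  cfg$ccd$frameStart <- 9000
  cfg$ccd$frameEnd <- 10800
  sim <- simulateExperiment(cfg, seed = 3, noise = FALSE)
  total <- apply(sim$stack@frames, 3, sum) -
    cfg$ccd$darkLevel * prod(dim(sim$stack@frames)[1:2])
  fit <- fitFreeHalflife(frameTimes(sim$stack), total,
                         exposure = frameExposures(sim$stack),
                         nComponents = 1, init = 1000)
  expect_equal(fit$halfLives[1], 1222, tolerance = 0.02)
})

test_that("PET truth conserves counts, adds over windows, needs t >= 0", {
  obj <- quartzObjects()
  map <- buildEnergyDepthMap(obj$material, obj$beam,
                             depthStep = obj$ccd@pixelPitch,
                             maxDepth = obj$ccd@depthExtent)
  pr <- productionRateProfile(defaultTruthModel(), map, obj$beam,
                              obj$material)
  # zero-width window -> zeros
  p0 <- renderPetTruth(pr, obj$components, obj$beam, c(60, 60))
  expect_true(all(p0@raw == 0))
  # additivity of disjoint windows
  pa <- renderPetTruth(pr, obj$components, obj$beam, c(0, 300), psfFwhm = 0)
  pb <- renderPetTruth(pr, obj$components, obj$beam, c(300, 900),
                       psfFwhm = 0)
  pc <- renderPetTruth(pr, obj$components, obj$beam, c(0, 900), psfFwhm = 0)
  expect_equal(pa@raw + pb@raw, pc@raw, tolerance = 1e-12)
  # counts over (0, infinity) with PSF off = atoms produced x branching
  pinf <- renderPetTruth(pr, obj$components, obj$beam, c(0, 1e9),
                         psfFwhm = 0)
  nProtons <- protonRate(obj$beam) * obj$beam@irradiationDuration
  for (iso in pr$isotopes) {
    atoms <- atomsAtEndOfIrradiation(pr$rate[, iso], obj$components[[iso]],
                                     obj$beam@irradiationDuration)
    expect_equal(pinf@perIsotope[, iso],
                 atoms * obj$components[[iso]]@branchingRatio / nProtons,
                 tolerance = 1e-9)
  }
  expect_error(renderPetTruth(pr, obj$components, obj$beam, c(-10, 60)),
               "simulated span")
})
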