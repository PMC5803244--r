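# Shared fixtures, built in code.  The "small" configuration keeps the
# full-physics depth axis (the anchor needs the 35 MeV region) but images a
# narrow lateral strip and uses merged 15 s exposures so a complete
# closed-loop run stays fast.

smallConfig <- function(exposure = 15, lateralExtent = 0.3) {
  cfg <- defaultRunConfig(lateralExtent = lateralExtent)
  cfg$ccd$exposure <- exposure
  cfg
}

quartzObjects <- function(cfg = smallConfig()) configObjects(cfg)

# noiseless single-depth light curve on the frame cadence, in the
# amplitude convention of the decomposition (counts per frame =
# sum_i a_i (e^{-lambda t1} - e^{-lambda t2}))
syntheticLightCurve <- function(amplitudes, components, time, exposure = 5) {
  t2 <- time + exposure
  counts <- numeric(length(time))
  for (i in seq_along(components)) {
    lam <- decayConstant(components[[i]])
    counts <- counts + amplitudes[i] * (exp(-lam * time) - exp(-lam * t2))
  }
  counts
}

seriesFromMatrix <- function(intensity, variance, time, exposure = 5,
                             depthStep = 0.0133) {
  depthProfileSeries(intensity, variance,
                     depth = (seq_len(nrow(intensity)) - 0.5) * depthStep,
                     time = time, exposure = exposure)
}

pstarWater <- function() {
  read.delim(system.file("extdata", "pstar_water.tsv",
                         package = "CherenkovXS"), comment.char = "#")
}

syntheticStoppingReference <- function() {
  read.delim(system.file("extdata", "stopping_reference_synthetic.tsv",
                         package = "CherenkovXS"), comment.char = "#")
}
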