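---
title: "Measuring proton-activation cross sections from Cherenkov decay imaging"
author: "CherenkovXS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring proton-activation cross sections from Cherenkov decay imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CherenkovXS)
```

## The measurement

Proton therapy deposits most of its dose at the Bragg peak, and verifying
*in vivo* where that peak actually sat is a standing problem.  PET imaging
after irradiation sees the positron emitters created by nuclear
fragmentation along the beam path — in tissue dominantly ¹⁵O, ¹³N and ¹¹C
from ¹⁶O — but the activation profile is not the dose profile: relating
the two requires the excitation functions σ(E) of the producing reactions,
which are sparsely and inconsistently measured below 70 MeV.

This package implements a method that extracts all three oxygen excitation
functions from a single irradiation.  A transparent, oxygen-bearing target
(synthetic fused quartz, SiO₂) is irradiated with a ~72 MeV pencil beam;
afterwards an EM-CCD camera images the faint Cherenkov light emitted by
the decay positrons.  Three facts make the analysis work:

1. **Depth encodes energy.**  A proton entering at E₀ slows down
   deterministically, so each depth z corresponds to a proton energy E(z)
   through the stopping power: dE/dz = −ρ S(E).
2. **Time encodes identity.**  The three emitters have very different
   half-lives (122.2 s, 597.9 s, 1222 s), so the decay curve at each depth
   is a three-exponential mixture whose amplitudes identify the isotopes.
3. **Light encodes quantity.**  Cherenkov intensity is proportional to the
   local decay rate (with a per-isotope light yield set by the β⁺
   endpoint), so the resolved amplitudes are proportional to the number of
   atoms produced.

The relative excitation functions follow as
σᵢ(E(z)) ∝ Rᵢ(z) / (n_O Φ(z) Δz), and the single unknown overall scale is
fixed by matching the ¹⁵O maximum to the archival value
76.8 mbarn ± 2.45% at 35 MeV — one anchor normalizes all three channels
simultaneously.

## Pipeline and model, stage by stage

### Proton transport (`buildEnergyDepthMap`)

Stopping power is the Bethe formula with the full maximum-energy-transfer
kinematics and ICRU mean excitation energies (water 75 eV, SiO₂ 139.2 eV,
polyethylene 57.4 eV).  Shell and Barkas corrections are omitted: above
the 0.5 MeV validity floor they are sub-percent here, and the
implementation stays analytic and verifiable against the PSTAR tables
(the packaged water reference agrees within 2% over 5–80 MeV).  The
depth–energy map integrates dE/dz with a step-refined RK4 scheme (energy
change ≤ 2% per step) and accumulates the Bohr straggling variance with
the relativistic spin-0 factor; the straggling σ_E(z) becomes the energy
uncertainty attached to every extracted cross-section point.  Requesting
an energy below the floor, or a degrader thick enough to stop the beam,
is an error rather than an extrapolation.

Primary-flux attenuation uses a single removal cross section per atom,
Φ(z)/Φ₀ = exp(−n_tot σ_rem z), default 0.1 barn, which gives the familiar
~1%/cm in water at therapy energies.  The true correction applied by the
original analysis is not published; the exponential-removal form and its
knob are therefore exposed as configuration, and the closed-loop tests use
the same model on both the generating and analyzing side.

### Synthetic data (`simulateExperiment`)

The generator stands in for the accelerator, target and camera, producing
frame stacks with known ground truth.  Its defaults are the experimental
conditions: 72.0 MeV, 30 nA, 30 min irradiation of a 3.5 cm quartz target;
133 µm pixels; 5 s exposures on a 5 s cadence from 120 s to 3600 s after
the end of irradiation; beam FWHM 0.400 × 0.246 cm.

- **Truth curves.**  Parametric shapes emulating the measured excitation
  functions: ¹⁵O as a smooth log-normal peak of exactly 76.8 mbarn at
  35 MeV above a 16.6 MeV threshold; ¹³N as a straggling-broadened
  resonance complex (Gaussians at 8, 13 and 16.3 MeV peaking near
  50 mbarn — a factor ~3 below the sharp archival resonance peaks, which
  is the reported effect of the energy resolution) plus a slow (p,2p2n)
  rise above 30 MeV; ¹¹C as a sharp sigmoid rise over 30–45 MeV to a
  ~22 mbarn plateau.  The ¹³N complex is deliberately centered at
  15–18 MeV: that is the energy band the reported late-window positron
  maximum at 3.6–3.7 cm in water maps to, and it makes ¹³N dominate the
  late PET windows as observed.  All shapes are configurable; tests
  assert only thresholds and ordering.
- **Activation.**  Build-up and decay follow the closed form
  A(t) = R (1 − e^{−λ t_irr}) e^{−λ t}; the rendered frame counts use the
  exact integral of e^{−λt} over each exposure — at 122.2 s half-life a
  midpoint evaluation of a 5 s frame would already bias ¹⁵O at the
  percent level.  ¹⁴O (70.62 s) is excluded by default: the analysis
  window starts at 120 s precisely so that it and the fast
  silicon-derived emitters have died away; a flag re-enables it as a
  nuisance component.
- **Optics and noise.**  Per-isotope light yields come from the Frank–Tamm
  weighted β⁺ spectrum (below), depth profiles are blurred with the
  positron-range kernel, spread laterally with the beam's Gaussian, offset
  by a 100-count dark level, Poisson-sampled and smeared with 10-count
  Gaussian read noise.  The counts scale of the real camera is arbitrary;
  the default detection probability of 3×10⁻⁵ per emitted photon is the
  geometric acceptance of the described optics (an f/1.4, 16 mm lens at
  50 cm subtends ≈3.3×10⁻⁵ of the sphere, times quantum efficiency and
  transmission ≈0.8).  EM-gain excess noise is not modeled (it was not
  characterized); identical seeds reproduce stacks bit for bit.

What the generator does *not* emulate: 3-D optical transport (refraction,
vignetting), the shallow-edge viewing-angle artifact (the pipeline still
masks the first 0.12 cm as the real analysis must), straggling smearing of
the production profile itself, and lateral beam scattering.  Passing
closed-loop tests therefore demonstrate the correctness of the inference
chain under the stated noise model, not robustness to uncalibrated camera
systematics.

### Preprocessing (`preprocessStack`)

Mean-dark subtraction (refusing to run without dark frames), an exact 2-D
median filter per frame (default 3×3; the original processing names the
filter but not its window), projection over a lateral ROI (default ±2
beam-FWHM around the auto-detected centroid), and masking of depths
shallower than 0.12 cm, where the finite target size makes the image
artificial.  Variances propagate through subtraction and projection
exactly; through the median filter the per-pixel variance is carried
unchanged, because for the lateral *sums* used downstream the
smoothing-induced correlation between neighbors approximately cancels the
per-pixel reduction.  Frames may be merged in exposure-weighted groups to
equalize late-time SNR.

### Decay decomposition (`fitFixedLambda`)

With half-lives fixed at the library values the per-depth fit is linear:
weighted least squares on the design matrix whose columns are the
per-frame decay fractions e^{−λᵢt₁} − e^{−λᵢt₂}.  The amplitude aᵢ is
thus the (yield-weighted) number of atoms present at the end of
irradiation — the natural reference, since the activation closed form
inverts it directly.  The solution, covariance (XᵀWX)⁻¹ and χ² are exact;
an optional nonnegativity constraint solves the three-component
best-subset problem by enumeration for low-SNR deep bins.  A
free-half-life variant (variable projection + Levenberg–Marquardt) exists
to *validate* that data on this cadence encode the known half-lives; it
is not part of the production chain, and a component with zero fitted
amplitude is flagged unidentifiable rather than given a fabricated
half-life.

### Cherenkov model (`cherenkovYieldFactor`, `buildBlurKernel`,
`deconvolveProfile`)

The relative light yield per decay integrates a simplified allowed β⁺
spectrum (statistical shape, no Fermi function) above the Cherenkov
threshold of the medium, weighted by the Frank–Tamm photon count over
400–800 nm.  The simplification is adequate because only yield *ratios*
between three similar nuclei enter the analysis.  The blur along depth —
Cherenkov light is emitted all along each positron track — is modeled as
a symmetric Laplacian kernel whose scale is half the positron CSDA range
(Katz–Penfold) at the spectrum's mean energy; the original analysis does
not specify its kernel, so family and scale are configuration.  The blur
is inverted per isotope with Richardson–Lucy (default 50 iterations, a
fixed count rather than a convergence test, for determinism), which
preserves nonnegativity and conserves counts to machine precision.
Deconvolution follows decomposition, matching the original order of
operations.

### Extraction and anchoring (`extractCrossSections`)

Amplitudes are inverted through the saturation factor
(Rᵢ ∝ aᵢ λᵢ / [yᵢ (1 − e^{−λᵢ t_irr})], with expm1 guarding small
λ t_irr), deblurred, divided by n_O Φ(z) Δz, and mapped to the energy
axis (restricted to 5–70 MeV, points past the Bragg peak dropped).  The
¹⁵O maximum is located by quadratic interpolation around the discrete
argmax — grid-step robustness — and one global factor scales all three
tables so that this maximum equals the anchor; the anchor's 2.45%
relative uncertainty is folded into every point in quadrature (the
original report does not say whether it was propagated per point or
stated once; propagating is the conservative choice).  The ¹³N resonance
region is reported as straggling-broadened, with no unfolding attempted:
the same broadening affects actual therapy beams, so the broadened curve
is the clinically relevant one.  Fractional amplitude uncertainties are
carried across the (count-conserving) deconvolution unchanged — a
linearization that ignores RL error correlations between neighboring
bins.

### PET forward model (`forwardPositronProfile`)

A deterministic one-dimensional activation model, not a Monte Carlo
transport calculation: positrons per incident proton per depth bin in a
time window are Σᵢ σᵢ(E(z)) n_O Δz (Φ(z)/Φ₀) ×
(1−e^{−λᵢt_irr})/(λᵢt_irr) × (e^{−λᵢt₁}−e^{−λᵢt₂}) bᵢ, smeared with the
PET's 2.0 mm FWHM Gaussian PSF.  The comparison quantity is emitted
positrons (the standard axis of PET range-verification comparisons); detector efficiency and
sinogram-level effects are out of scope.  Water is treated as pure (the
2% gelatin and the thin entrance film are neglected, I = 75 eV).
Profile comparison reports per-bin z-scores and the fraction within 1σ.

## Numerical choices and degenerate inputs

- Depth grids are bin centers from the entrance face at the camera pitch
  (133 µm); energies MeV, times s, cross sections mbarn, everywhere.
- The energy–depth map refuses energies below 0.5 MeV (Bethe validity);
  the CSDA range closes the last 0.5 MeV with the R ∝ E^1.77 power law
  (sub-µm error at these energies).
- Degenerate decomposition designs (duplicate half-lives) fail naming the
  collinear pair; fits require ≥3 frames per component.
- RL deconvolution clips negative inputs to zero (documented), treats an
  all-zero profile as already converged, and renormalizes the total each
  iteration to absorb floating-point drift.
- Edge-truncated kernels (blur and PSF) are column-renormalized so
  convolution conserves totals on the finite grid.
- Quadratic peak interpolation falls back to the grid argmax at the grid
  boundary or under non-concave fits.

## Problem sizes used by the test suites

The closed-loop suites keep the full physics (3.5 cm depth axis at 133 µm,
the 5 s cadence over 120–3600 s) but image a narrow lateral strip —
0.5 cm for the 100-seed recovery suite, 0.3 cm with 15 s exposures for
unit-level loops — which preserves per-depth-bin statistics while keeping
a complete simulate-and-extract cycle at a few seconds.  The recovery
criterion is the median over 100 seeds of the relative RMS deviation from
truth across 20–65 MeV, evaluated where the truth curve exceeds 10% of
its peak (below that, relative error against a near-zero truth is not a
meaningful statistic).

## Known limitations

- The flux-correction form, blur-kernel family and median window are
  assumptions where the original analysis is unspecified; all are exposed
  as configuration, and wrong choices bias the deep/low-energy end first.
- The anchor transfers the archival point's scale *and* its error floor;
  nothing below 2.45% fractional uncertainty can come out of the chain.
- Dark-mean estimation noise is an offset shared across frames; the
  per-frame variance model does not represent it, so with few dark frames
  the slow (¹¹C) amplitudes absorb a small correlated bias.
- The forward model is 1-D: lateral scattering and secondary protons are
  outside scope, consistent with comparing depth profiles only.
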