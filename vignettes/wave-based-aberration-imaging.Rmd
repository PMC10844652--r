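---
title: "Wave-based photoacoustic imaging through a thick aberrating layer"
author: "pawave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-based photoacoustic imaging through a thick aberrating layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pawave)
```

## The problem

Photoacoustic tomography reconstructs a map of optical absorption from the
ultrasound that laser-excited absorbers emit.  When a thick layer with a
strongly different sound speed -- skull bone, a Perspex slab -- sits between
the absorbers and the receiving array, the recorded wavefronts are delayed
and distorted.  Conventional delay-and-sum (DAS) beamforming, which assumes
a single sound speed, then paints the target at the wrong depth with a
corrupted shape.  When the speed contrast is large (water 1540 m/s against
bone-like 2700 m/s, a 75% jump) and the layer thickness is comparable to
the acoustic wavelength, ray corrections are not enough: diffraction
dominates, and a wave model is needed.

`pawave` implements a scalar-wave computational pipeline for this setting
in two dimensions:

1. a **forward model**: a Fresnel--Kirchhoff diffraction sum adapted to a
   two-speed layered medium,
2. three **beamformers** (wave-based, DAS, straight-ray) for image
   formation when the layer profile is known,
3. a **pulse-echo estimator** of the layer profile from a single
   transmit--receive acquisition, and
4. a **joint inversion** (`pa_fit()`) that recovers the layer thickness
   profile and the target image simultaneously from the RF traces when the
   profile is not known exactly.

## The forward model

The medium is split at the interface `z = z(x)` into an aberrating layer
(sound speed `ca`, between the flat array at `z = 0` and the interface) and
water (`cw`, beyond it).  Every interface sample `j` acts as a secondary
Huygens wavelet source.  A point absorber `s` with initial pressure `a_s`
contributes to element `n` the signal

    p_n(t) = sum_s sum_j a_s * psi_sjn / (r_sj * r_jn)
             * h(t - r_sj/cw - r_jn/ca)

where `r_sj` and `r_jn` are the two segment lengths, `h` is the element
impulse response, and `psi` is the obliquity factor.  Four obliquity
variants are provided: the speed-weighted Kirchhoff form
`N.r_sj/cw + N.r_jn/ca`, the two Rayleigh--Sommerfeld cosines, and the
constant 1.  They weight the angular spectrum differently but produce
nearly identical images; the package default is `"kirchhoff"`, and the
proportionality constant is left un-normalized because all reconstructions
are relative-amplitude.

Discretization choices that matter:

* **Interface sampling.**  One interface point above each array element
  (spacing = array pitch, 1 mm) for reconstruction.  The sum carries the
  lateral spacing as a quadrature weight so that refining the interface
  sampling does not change the amplitude scale.
* **Delay deposition.**  Each wavelet is deposited onto the time grid by
  linear interpolation between the two neighbouring samples, and each
  trace is convolved once with the kernel (FFT, zero-phase).  Linear
  deposition keeps quantization artifacts small and makes the model
  differentiable in the thicknesses through the interpolation weights.
* **Degenerate geometry.**  Distances below one interface spacing raise an
  error instead of being clipped silently.
* **Attenuation** is available as scalar per-medium coefficients at the
  centre frequency multiplying each wavelet by
  `exp(-alpha_w r_sj - alpha_a r_jn)`; it defaults to zero, and full
  frequency dependence is out of scope.

The sensor response is a Gaussian band-pass kernel: centre frequency 1 MHz,
75% fractional bandwidth, read as the -6 dB full width of the power
spectrum (the usual ultrasound convention; the reference level is not
standardized, and this is the choice the package pins with a test).  The
default sampling rate is 20 samples per centre period (20 MHz); the default
trace length covers the largest two-segment delay plus four envelope
standard deviations of the kernel.

Noise is specified as mean-to-mean SNR: `10*log10` of mean signal intensity
over mean noise intensity, so 3.0 dB corresponds to noise intensity equal
to half the signal intensity.  Noise is seeded and bit-reproducible.

## Beamforming

With a known profile, `beamform_wave()` back-projects the traces through
the same diffraction geometry.  Two weightings are provided, because the
analytic back-projection of the forward kernel is not its adjoint:

* `mode = "analytic"` (default): weight `r_sj * r_jn * psi`, the
  analytic back-projection formula;
* `mode = "adjoint"`: correlate with the kernel, weight
  `psi/(r_sj r_jn)` -- the exact transpose of `simulate_rf()`, which the
  test suite pins with a dot-product identity at 1e-6, and which the
  inversion uses internally.

`beamform_das()` and `beamform_straight_ray()` implement the homogeneous
and refraction-free layered references.  On a flat fast layer the three
reconstructions order exactly as the physics says they must: DAS places
the target several millimetres too shallow (the time saved in the fast
layer is mapped with the slow water speed), the straight-ray model fixes
the depth but not the shape, and the wave model is diffraction-limited.
Time lookups use linear interpolation (matching the forward deposition);
out-of-window lookups contribute zero and are counted, with a metadata
warning when more than half the contributions are clipped.

Images retain the signed beamformed sum internally and display the
absolute value; argmax-based checks are insensitive to this choice.

## Echo-based profile estimation

`estimate_profile_echo()` implements the simplified companion measurement:
a normal-incidence pulse-echo acquisition reflects off the layer's distal
facet; matched filtering each trace with the transmit kernel and picking
the strongest in-window peak gives the round-trip time, hence
`z = ca * tau / 2` per element.  The search window (from the expected
thickness range) is what rejects reverberation replicas, which arrive at
integer multiples of the round trip with smaller amplitude; a parabolic
refinement of the correlation peak gives sub-sample timing.  Elements whose
peak falls below a quarter of the median confidence are interpolated from
their neighbours.

## Joint inversion

When the profile is unknown, `pa_fit()` minimizes

    L(theta) = D(theta) + P(theta),      theta = ({z_j}, {a_s})

where `D` is the summed squared residual between the forward model and the
measured traces over all elements and samples, and

    P = alpha * sum_s |a~_s| + beta * sum_j (z_j - z_init_j)^2

combines an L1 sparsity prior on the amplitudes -- directly for sparse
point targets, or on the modulus of the unitary 2-D discrete Fourier
transform for targets (vessels) that are compressible in the Fourier
domain -- with an L2 anchor of the thicknesses to their initial estimate.

The minimization is ADAM gradient descent.  Because no automatic
differentiation framework is available in R, the gradient is hand-derived
and exact for the discretized model: an adjoint-state computation that
back-propagates the residual through the kernel correlation and
accumulates, per wavelet, the derivative of the weight and of the delay
(including the dependence of surface normals on neighbouring thicknesses
through the finite-difference slope).  The test suite pins it against
central finite differences at 1e-4 relative error per coordinate; the
L1 subgradient at zero is taken as zero, with no proximal step.

Numerical choices:

* **Per-block step sizes.**  Thicknesses (metres) and amplitudes
  (arbitrary pressure units) differ by orders of magnitude; ADAM's
  per-coordinate normalization makes steps unit-free, so the two learning
  rates are expressed directly in parameter units: `lr_z = lambda/50` per
  iteration, and `lr_a` = 1/20th of the least-squares back-projection
  scale -- the adjoint image of the data divided by the energy of a
  single-pixel forward response, which estimates the amplitude magnitude
  regardless of the obliquity variant's overall scale.
* **Projections.**  `z >= 0` always; `a >= 0` by default (initial
  pressure is physically non-negative), releasable.
* **Default priors** are data-scaled: `alpha = 0.01 * D0 / a_hat` with
  `D0` the data energy and `a_hat` the back-projection amplitude scale,
  and `beta = 0.01 * D0 / (J * lambda^2)` with `J` the number of
  interface samples; both are exposed in `pa_prior()` (`NA` requests the
  default).
* **Stopping.**  Fixed budget of 100 iterations plus an early stop when
  the relative loss change stays below 1e-6 for 10 iterations; a
  divergence guard aborts with the history if the loss exceeds 1000x its
  initial value for 10 consecutive iterations.
* **Frequency continuation (optional).**  The raw-trace L2 misfit is
  oscillatory in each thickness with period `1/(f0 (1/cw - 1/ca))` --
  about 3.6 mm at 1 MHz for water/bone -- so initial thickness errors
  beyond roughly half that wrap the phase (the cycle-skipping problem of
  waveform inversion).  `pa_control(stages = ...)` can schedule stages
  that low-pass both the data and the model kernel (widening the basin)
  before refining at full bandwidth, with the prior weights scaled by the
  in-band energy and a warm-up during which the thickness block is frozen
  while the image forms.  The default is the plain single-stage,
  full-bandwidth optimization.

### Operating regime and a known limitation

The joint problem has a structural degeneracy: a smooth thickness error
displaces the apparent source positions, and a displaced source
distribution reproduces the data of a wrong profile to first order.  What
breaks the tie is the sparsity prior and the across-array curvature of the
arrival times -- second-order information.  Combined with the phase
wrapping above, this makes the thickness channel the hard part of the
inversion.  In the package's own synthetic studies the fit always drives
the loss to a plateau within the iteration budget and reconstructs the
target support, and it refines the profile when the initial error is a
fraction of a wavelength (the regime of an echography-derived initial
guess -- the intended workflow); initial errors approaching or exceeding
a wavelength, however, are not reliably corrected: gradient descent
settles in a compensated or cycle-skipped local minimum, with or without
frequency continuation.  The test suite exercises both regimes and
reports the hard one honestly rather than weakening the check.

## The synthetic study

`make_scenario()` reproduces the structure of the numerical study: a
65-element, 1 mm pitch linear array in contact with the layer, water at
1540 m/s, layer at 2700 m/s (bone-like; the experiment-like scenario uses
2775 m/s and 128 elements), a 1 MHz / 75% Gaussian response, and 3.0 dB
mean-to-mean SNR:

* `points65`: 25 point absorbers (5 x 5 grid, 4 mm spacing, 40 mm deep)
  behind a lens-like layer (5 mm edges, 15 mm centre), image grid
  128 x 128 over 64 x 64 mm;
* `sparse20`: 20 points (4 x 5) behind a flat 10 mm layer carrying a
  smooth Gaussian bump (amplitude two wavelengths, 8 mm lateral SD),
  image grid 64 x 64 over 32 x 32 mm at 0.5 mm pitch -- the
  joint-inversion benchmark, initialized from the flat profile;
* `vessels`: random smooth vessel branches with sub-wavelength widths and
  a rounded swelling, the Fourier-sparsity regime.

Because the reference study generated its data with an independent
full-wave solver, and this package generates its own, the scenario
generator mitigates the "inverse crime" in three selectable ways: data are
synthesized with a 4x finer interface sampling than reconstruction, with a
different obliquity variant (Rayleigh--Sommerfeld I against the Kirchhoff
reconstruction default), and with calibrated noise.  What the phantoms do
*not* emulate: full-wave propagation effects (internal reverberations,
mode conversion, frequency-dependent attenuation), elevational (3-D)
spreading, and element directivity.  Passing tests therefore demonstrate
the correctness and the conditioning of the reconstruction machinery, not
its robustness to every physical effect present in real recordings.

Problem sizes in the tests and the acceptance script are the scenario
sizes above: they keep a full sparse20 inversion around two minutes on a
single core, and the whole pipeline comfortably reproducible on a laptop.

## Worked example

```{r example, eval = FALSE}
sc  <- make_scenario("sparse20", seed = 1)
rf  <- scenario_rf(sc)                      # "measured" traces, 3 dB SNR
img <- beamform_wave(rf, sc$profile, sc$medium, sc$array, sc$grid)

fit <- pa_fit(rf, scenario_model(sc), z_init = sc$z_init,
              truth = sc$profile)
summary(fit)
plot(fit, "loss"); plot(fit, "profile"); plot(fit, "image")
```

## Limitations

* 2-D imaging plane only; flat contact array at the layer's flat face.
* Single homogeneous layer, single refraction; no shear-wave conversion,
  no reverberation synthesis.
* Scalar attenuation at the centre frequency; no dispersion.
* Joint inversion: see the operating-regime discussion above -- initial
  profile errors beyond about a wavelength are outside the reliable
  recovery regime, matching the intended workflow in which the initial
  guess comes from the pulse-echo measurement.
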