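---
title: "Models and methods behind dffocm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dffocm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dffocm)
```

# The imaging problem

Full-field optical coherence microscopy (FF-OCM) images an en-face plane of
a scattering sample with a camera behind a Linnik interferometer: only light
whose sample-arm path matches the reference arm within the source coherence
length interferes, which gates the detected signal to a thin depth slice.
The *dynamic* variant (d-FF-OCM) switches the phase-stepping actuator off
and instead exploits intrinsic subcellular motion: nanometre-scale axial
displacements of scatterers modulate the interferometric phase, producing
temporal intensity fluctuations on the camera. The fluctuation strength and
its frequency content differ between tissue structures, giving a
fluorescence-like functional contrast without labels.

This package implements the complete processing chain for that modality —
static four-phase reconstruction, the dynamic per-pixel spectral pipeline,
resolution and contrast metrics, and the coherence-gate bookkeeping needed
when focusing deep through a refractive-index mismatch — together with a
synthetic interferometer that generates raw stacks with known ground truth,
so every stage can be validated quantitatively without instrument data.

# Signal model of the synthetic interferometer

Each camera pixel is modelled as a scalar two-beam interference signal with
a single effective scatterer:

$$I(t) = I_r + I_s + 2\sqrt{I_r I_s}\; V(\Delta(t))\,
         \cos\!\big(\phi_0 + 4\pi\,\delta z(t)/\bar\lambda\big),$$

where $I_r$ and $I_s$ are the reference- and sample-arm returns in
photoelectrons per frame, $V$ is the fringe-visibility envelope of the
partially coherent source, $\Delta(t)$ the double-pass optical path
mismatch, $\phi_0$ the static interferometric phase, and $\delta z(t)$ the
axial scatterer displacement. The $4\pi/\bar\lambda$ factor is the
double-pass phase sensitivity of a reflection geometry. The envelope is
Gaussian in the mismatch, $V(\Delta) = \exp(-4\ln 2\,\Delta^2/l_c^2)$, with
$l_c$ the coherence length (FWHM); the displacement enters the envelope
argument as $2\,\delta z(t)$ and the gate terms (stage displacement,
reference offset) likewise double-pass.

Deliberate simplifications: the model is paraxial and single-scatterer per
pixel, with no speckle, no multiple scattering, and no NA-dependent PSF —
a spatially incoherent source suppresses cross-pixel coherence in the real
instrument, and the processing chain under test operates strictly per
pixel, so spatial optics add nothing to what the tests can falsify. The
simulator therefore validates the *temporal* signal chain; claims about
spatial resolution on real tissue are outside what passing tests show.

Scatterer dynamics are prescribed per labelled region as a sum of
sinusoidal components (frequency, displacement amplitude in nm, phase) plus
optional band-limited Gaussian displacement noise, a stand-in chosen
because the true spectrum of subcellular motion is not characterized; it
is a test harness, not a biological model. Camera detection is Poisson
shot noise at photoelectron scale, clipping at the full-well capacity, and
optional quantization to the digitizer bit depth. Dynamics and shot noise
draw from independent seed-derived substreams, so the displacement
realization is identical with noise toggled on or off, and a fixed
specification reproduces stacks bit-identically.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| frame rate | 500 Hz | instrument acquisition rate; sets the 250 Hz Nyquist limit of the spectral analysis |
| stack length | 512 frames | one acquisition block; ~0.98 Hz spectral bin spacing |
| pixel pitch | 120 nm | sample-plane pixel size of the 100x system |
| $\bar\lambda$, $\Delta\lambda$ | 600 nm, 200 nm | white light above a 490 nm cut-on filter |
| coherence length $l_c$ | $\frac{2\ln 2}{\pi}\bar\lambda^2/\Delta\lambda \approx 794$ nm | Gaussian-spectrum relation, derived from the source defaults |
| full well | $2\times10^6$ e$^-$ | high-FWC camera; sets the shot-noise-limited SNR ceiling |
| reference intensity | 10% of full well | reference arm attenuated to 10% in double pass to optimize SNR |
| sample reflectivity | 0.05 of the reference return | weak-scatterer regime typical of tissue |
| $\phi_0$ | $\pi/2$ | quadrature: intensity is first-order sensitive to $\delta z$ |
| drive amplitude (fixtures) | 30 nm | phase excursion $4\pi a/\bar\lambda \approx 0.63$ rad: strong but sub-fringe modulation |
| $n_s$, $n_{imm}$ | 1.40, 1.515 | soft tissue under oil immersion |

# Stack normalization

Source power fluctuations multiply whole frames; before spectral analysis
each frame is divided by its spatial mean and rescaled by the grand mean of
all frame means. This equalizes per-frame means, preserves the global
stack mean, removes pure multiplicative flicker exactly, and is idempotent.
How the original instrument normalized (spatial mean, reference ROI, or a
photodiode) is not public; the spatial-mean form was chosen as the simplest
operation that removes multiplicative source noise without altering spatial
contrast. Camera nonlinearity is handled separately by an optional
caller-supplied monotone response map (function or two-column LUT), applied
pointwise before gain equalization; the default is the identity.

# Static reconstruction

With the piezo stepping the phase by $90^\circ$ per frame, the fringe
amplitude is demodulated as
$\sqrt{(I_1-I_3)^2 + (I_2-I_4)^2}$, which equals $2B$ for an ideal quad
$I_k = A + B\cos(\phi_0 + k\pi/2)$ — independent of the incoherent
background $A$ and the phase $\phi_0$. The operation is kept free of any
dark-frame subtraction or normalization so the identity is exact and
testable in isolation.

# The dynamic pipeline

Each pixel's time series is analysed two ways: the temporal standard
deviation (sample SD, denominator $T-1$) gives a scalar
fluctuation-strength map, and a pixel-by-pixel FFT gives a one-sided
fluctuation spectrum. Spectral conventions, chosen once for
reproducibility:

* **Rectangular window, no zero padding.** Bin spacing is exactly
  `frame_rate / n_frames` (0.977 Hz for the 500 Hz / 512-frame default).
* **Parseval scaling.** Magnitudes are scaled so that the sum of squared
  one-sided AC magnitudes equals the population temporal variance; a unit
  cosine at an interior bin has magnitude $1/\sqrt 2$ (its RMS). This makes
  variance conservation an exact machine-precision test.
* **DC exclusion.** The DC bin stays in the cube but never enters band
  integrals: static brightness must not leak into dynamic contrast.
* **Band membership.** Bins belong to a band when their centre frequency
  lies in half-open $[f_{lo}, f_{hi})$; a tie at a shared edge goes to the
  upper band; a band whose upper edge equals Nyquist includes the Nyquist
  bin, so bands tiling $(0, f_{Nyq}]$ partition all AC bins.
* **Integrated quantity.** Magnitude integration is the default rendering
  quantity; power mode is provided and is the one that satisfies exact
  band-partition conservation. Which of the two the original pipeline used
  is not stated; both are one flag apart.

The three band integrals (defaults 1–3, 3–100, 100–250 Hz) map to blue,
green and red. The edges emphasise slow, intermediate and fast subcellular
motion and are configurable: rendered images are fairly stable under
moderate re-binning, and short stacks need wider low bands (a 128-frame
stack has no bins below 3.9 Hz — the package warns and renders a zero
channel in that case).

Rendering applies $\log_{10}(v + \varepsilon)$ with
$\varepsilon = 10^{-12}\max(v)$ (floor $10^{-30}$) — small enough to be
invisible for populated maps while defining the transform at zero — then a
percentile contrast stretch: values at or above the
$(100-p_{hi})$-th percentile (default $p_{hi}=1$) render exactly 1, at or
below the $p_{lo}$-th percentile (default 1) exactly 0, linear in the log
domain between. Percentiles use linear interpolation over sorted values
(R's type-7 quantile); on a map of all-distinct values the saturated
fraction is then exactly $p_{hi}$ per cent. A channel with no dynamic range
after the log transform renders all-zero with a warning. Volumes are
assembled by stacking en-face images over depth with per-channel
maximum-intensity projections along each axis.

# Resolution and contrast metrics

**Fourier ring correlation.** Rings are one frequency bin wide, defined on
the integer radius of the centred discrete spectrum; images are
mean-subtracted before their FFTs are correlated ring by ring. Two
threshold criteria are provided: the fixed 1/7 line (default) and the
half-bit curve; the resolution is the pixel pitch divided by the first
threshold crossing, linearly interpolated between rings. If the curve
never drops below the threshold, the resolution is beyond the Nyquist
limit of the pixel sampling and is reported as `NA` with a flag rather
than a number. For a single acquisition, `split_stack_frc()` applies the
standard split-data protocol: odd and even frames are processed as two
independent half-stacks and the FRC is taken between the two band-sum
images. Which split and threshold the original analysis used is not
public; these defaults are the package's own documented choice.

**Contrast-to-noise ratio.** Defined here as
$|\mu_{sig}-\mu_{bg}|/\sigma_{bg}$ with the background SD on $N-1$; scale-
and offset-invariant. The original report's exact CNR formula is not
public either, so this common definition is used and stated explicitly.

# Coherence-gate tracking

Moving the sample stage by $\Delta z$ toward the objective through
immersion of index $n_{imm}$ places the focus at depth
$\Delta z\, n_s/n_{imm}$ in a sample of index $n_s$, while the coherence
gate moves differently because optical path scales with index. Keeping
both gates co-located requires a single-pass reference-arm change of
$\Delta z\,(n_s^2-n_{imm}^2)/n_{imm}$ — about $-0.22\,\mu m$ per micrometre
for tissue (1.40) under oil (1.515), the reference path shortening. The
model is deliberately paraxial even though the optics are NA 1.25: the
calibration procedure itself reduces the problem to a single empirical
linear slope under a homogeneous-index assumption, and that 1-D abstraction
is what the package mirrors. Sign conventions: positive stage displacement
moves the sample toward the objective; positive reference offset lengthens
the reference path.

`calibrate_gate()` reproduces the instrument procedure: displace the stage
(default 30 µm), sweep the reference offset over a grid, score each offset
by the mean demodulated fringe amplitude, and take the argmax. The
recovered slope matches the closed form within one grid step, and the
contrast-vs-offset curve is Gaussian with FWHM $l_c/2$ in offset (the
double-pass factor), so halving the coherence length halves the curve
width — both properties are tested.

# Numerical notes and degenerate inputs

* At large gate mismatch the fringe term underflows against the incoherent
  background ($2\sqrt{I_rI_s}\,V \ll$ double-precision ulp of $I_r+I_s$),
  so far tails of the contrast curve are exactly zero; unimodality of the
  curve holds on the numerically resolvable region, which is also the
  physically measurable one.
* Stacks are stored as multi-page TIFF with a JSON sidecar. The TIFF layer
  stores samples on a normalized scale, so float data are written through
  an affine encoding (offset and scale recorded in the sidecar) at 32 bits
  per sample — relative precision $2^{-31}$ of the data range; integer
  data up to 65535 round-trip bit-identically as uint16.
* A frame with zero spatial mean, stacks shorter than 2 frames (4 for
  spectra), non-square FRC inputs, a zero-variance CNR background, and
  drive frequencies at or above Nyquist all raise typed errors rather than
  propagating NaNs.
* Tests and examples run on reduced geometries (8–64 px, 64–512 frames),
  chosen so the whole validation suite executes in seconds while every
  spectral property (bin alignment, Nyquist closure, Parseval) is still
  exercised exactly; the conventions are resolution-independent.

# Known limitations

* The simulator's sinusoid/band-noise displacement model is a test
  vehicle; real subcellular fluctuation spectra are broadband and
  non-stationary, so passing hue tests demonstrates correct band mapping,
  not biological fidelity.
* No registration or motion gating: the pipeline assumes a mechanically
  stable stack, as for ex vivo tissue pressed against a coverslip.
* The gate model ignores high-NA vectorial focal-shift corrections and
  depth-dependent index variation; it calibrates a single linear slope.
* Flat-field and vignetting corrections are out of scope; the
  normalization removes temporal, not spatial, gain structure.
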