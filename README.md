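# dffocm

Processing chain for **dynamic full-field optical coherence microscopy
(d-FF-OCM)** — camera-based interferometric imaging that turns intrinsic
subcellular motion into label-free, fluorescence-like contrast. The package
is aimed at builders and users of FF-OCM instruments who need a validated,
scriptable reference implementation of the reconstruction pipeline, and at
anyone wanting to prototype dynamic-contrast analysis on simulated data
with known ground truth.

## What it computes

**Static reconstruction.** From four frames phase-stepped by 90°, the
conventional FF-OCM amplitude image

&nbsp;&nbsp;&nbsp;&nbsp;*A* = √((*I*₁ − *I*₃)² + (*I*₂ − *I*₄)²),

which equals 2*B* for fringes *I_k* = *A*₀ + *B* cos(φ₀ + *k*π/2),
independent of background and phase.

**Dynamic reconstruction.** With the phase actuator off, each pixel's
time series over a raw stack (default 512 frames at 500 fps) is
flicker-normalized, then analysed by temporal standard deviation and by a
per-pixel FFT. The one-sided fluctuation spectrum is integrated over three
frequency bands — low 1–3 Hz, mid 3–100 Hz, high 100–250 Hz by default —
which are log-transformed, percentile-stretched (top 1% saturated, bottom
1% zeroed per channel) and assembled into an RGB composite: blue = slow,
green = intermediate, red = fast motion. Volumes assemble from en-face
images with orthogonal maximum-intensity projections.

**Metrics.** Fourier ring correlation (fixed-1/7 or half-bit threshold,
split odd/even-frame protocol for single acquisitions) for resolution
estimation, and a contrast-to-noise ratio |μ_sig − μ_bg|/σ_bg.

**Gate tracking.** The reference-arm compensation slope
(*n_s*² − *n_imm*²)/*n_imm* needed to keep the coherence gate on the focal
plane when focusing through a refractive-index mismatch, plus a simulated
replica of the instrument calibration sweep.

**Simulator.** A synthetic Linnik interferometer: scalar two-beam signal
with a Gaussian coherence envelope, per-region prescribed scatterer
dynamics (sinusoids and band-limited displacement noise), Poisson shot
noise at photoelectron scale with a 2×10⁶ e⁻ full well, clipping and
quantization — fully seeded and bit-reproducible.

See `vignettes/dffocm-methods.Rmd` for the models, conventions and design
choices in detail.

## Worked example

Simulate three tissue regions oscillating at 2, 20 and 200 Hz and run the
dynamic pipeline:

```r
library(dffocm)

regions <- matrix(0L, 64, 64)
regions[, 1:21] <- 1L; regions[, 22:42] <- 2L; regions[, 43:64] <- 3L
dyn <- scatterer_dynamics(
  static_reflectivity = 0.05, regions = regions,
  components = list(
    list(region = 1, frequency = 2,   displacement_amplitude = 30),
    list(region = 2, frequency = 20,  displacement_amplitude = 30),
    list(region = 3, frequency = 200, displacement_amplitude = 30)),
  seed = 42)
stk <- simulate_stack(simulation_spec(meta = acquisition_meta(),
                                      dynamics = dyn))
stk
#> <raw_stack> 512 frames of 64x64 px @ 500 fps, range [156703, 263987]

img <- dynamic_pipeline(stk)
for (r in 1:3) {
  mask <- regions == r
  cat(sprintf("region %d: R %.2f G %.2f B %.2f\n", r,
      mean(img$rgb[1,,][mask]), mean(img$rgb[2,,][mask]),
      mean(img$rgb[3,,][mask])))
}
#> region 1: R 0.02 G 0.01 B 1.00
#> region 2: R 0.04 G 0.99 B 0.03
#> region 3: R 0.99 G 0.15 B 0.01
```

Each region's mean colour lands in the channel of its drive band: the 2 Hz
region is blue, 20 Hz green, 200 Hz red — the hue encodes the fluctuation
timescale. The `range` line shows the simulated camera operating around
2×10⁵ photoelectrons (reference arm at 10% of full well) with fringe
modulation on top.

Gate calibration for tissue (n = 1.40) under immersion oil (n = 1.515):

```r
calibrate_gate(simulation_spec(
  meta = acquisition_meta(n_frames = 4, height = 16, width = 16),
  dynamics = scatterer_dynamics(static_reflectivity = 0.05),
  n_sample = 1.40, n_immersion = 1.515, shot_noise = FALSE))
#> <gate_calibration> optimum offset -6.638 um over 30.0 um -> slope -0.2213 (model -0.2213)
```

The simulated contrast sweep recovers the paraxial closed form: the
reference arm must shorten by 0.22 µm per micrometre of stage displacement
to keep the coherence and confocal gates co-located.

A command-line front end wrapping the same functions lives at
`inst/cli/dffocm.R` (`simulate`, `reconstruct-static`,
`reconstruct-dynamic`, `frc`, `cnr`, `calibrate-gate`, `make-fixture`).

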