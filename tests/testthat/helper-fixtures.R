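# In-code fixture builders shared across the suite.

tiny_meta <- function(n_frames = 64, n = 8, fps = 500) {
  acquisition_meta(frame_rate = fps, n_frames = n_frames,
                   height = n, width = n)
}

# Stack whose every pixel carries a single sinusoidal tone, built directly
# (not via the simulator) so simulator tests have an independent reference.
tone_stack <- function(freq, amplitude = 1, offset = 10, n_frames = 64,
                       n = 4, fps = 500, phase = 0) {
  tt <- (seq_len(n_frames) - 1) / fps
  series <- offset + amplitude * cos(2 * pi * freq * tt + phase)
  raw_stack(array(rep(series, n * n), c(n_frames, n, n)),
            tiny_meta(n_frames, n, fps))
}

# Noise-free simulated stack with one region driven at one frequency.
driven_spec <- function(freq, amplitude = 20, n_frames = 512, n = 4,
                        seed = 1, shot_noise = FALSE, ...) {
  simulation_spec(
    meta = tiny_meta(n_frames, n),
    dynamics = scatterer_dynamics(
      static_reflectivity = 0.05,
      components = list(list(region = 1, frequency = freq,
                             displacement_amplitude = amplitude)),
      seed = seed),
    shot_noise = shot_noise, ...)
}

# Three vertical regions driven at the given frequencies.
three_region_spec <- function(freqs = c(2, 20, 200), n = 64,
                              n_frames = 512, amplitude = 30, seed = 1,
                              shot_noise = TRUE) {
  regions <- matrix(0L, n, n)
  b <- floor(seq(0, n, length.out = 4))
  for (i in 1:3) regions[, (b[i] + 1):b[i + 1]] <- i
  spec <- simulation_spec(
    meta = tiny_meta(n_frames, n),
    dynamics = scatterer_dynamics(
      static_reflectivity = 0.05, regions = regions,
      components = lapply(1:3, function(i)
        list(region = i, frequency = freqs[i],
             displacement_amplitude = amplitude)),
      seed = seed),
    shot_noise = shot_noise)
  list(spec = spec, regions = regions, freqs = freqs)
}

# Ideal four-step quad I_k = A + B cos(phi0 + (k-1) pi/2) as plain matrices.
ideal_quad <- function(A, B, phi0, n = 3) {
  mats <- lapply(0:3, function(k)
    matrix(A + B * cos(phi0 + k * pi / 2), n, n))
  phase_quad(mats[[1]], mats[[2]], mats[[3]], mats[[4]])
}
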