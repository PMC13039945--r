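#' Scatterer dynamics specification
#'
#' Ground-truth description of sub-resolution axial scatterer motion for the
#' interferometer simulator. Each labelled region of the field of view moves
#' coherently as a sum of sinusoidal displacement components and, optionally,
#' band-limited Gaussian displacement noise; the induced optical phase
#' modulation is what generates temporal intensity fluctuations on the
#' simulated camera.
#'
#' @param static_reflectivity Y x X matrix in `[0, 1]` (or a scalar,
#'   recycled): sample-arm return strength per pixel, expressed as a
#'   fraction of the reference-arm return.
#' @param regions Integer Y x X label matrix; label 0 is static background.
#'   `NULL` means a single region covering the whole field (label 1).
#' @param components List of components, each a list with fields `region`
#'   (label), `frequency` (Hz), `displacement_amplitude` (nm) and `phase`
#'   (rad, default 0). Several components may share a region.
#' @param band_noise Optional list (or list of lists) with fields `region`
#'   (default: all labelled regions), `f_lo`, `f_hi` (Hz) and
#'   `rms_displacement` (nm): filtered-Gaussian displacement noise confined
#'   to the given temporal band.
#' @param seed Integer seed; the same seed always yields the same
#'   displacement realization.
#' @return An object of class `scatterer_dynamics`.
#' @examples
#' dyn <- scatterer_dynamics(
#'   static_reflectivity = 0.05,
#'   components = list(list(region = 1, frequency = 20,
#'                          displacement_amplitude = 30))
#' )
#' @export
scatterer_dynamics <- function(static_reflectivity = 0.05,
                               regions = NULL,
                               components = list(),
                               band_noise = NULL,
                               seed = 1L) {
  if (any(static_reflectivity < 0) || any(static_reflectivity > 1))
    stop_parameter("static_reflectivity values must lie in [0, 1]")
  for (cmp in components) {
    if (is.null(cmp$frequency) || is.null(cmp$displacement_amplitude))
      stop_parameter("each component needs frequency and displacement_amplitude")
    if (cmp$frequency <= 0)
      stop_parameter("component frequencies must be positive")
    if (cmp$displacement_amplitude < 0)
      stop_parameter("displacement amplitudes must be >= 0")
  }
  if (!is.null(band_noise) && !is.null(band_noise$f_lo))
    band_noise <- list(band_noise)
  for (bn in band_noise) {
    if (bn$f_lo <= 0 || bn$f_hi <= bn$f_lo)
      stop_parameter("band_noise needs 0 < f_lo < f_hi")
    if (bn$rms_displacement < 0)
      stop_parameter("band_noise rms_displacement must be >= 0")
  }
  structure(
    list(
      static_reflectivity = static_reflectivity,
      regions = regions,
      components = components,
      band_noise = band_noise,
      seed = as.integer(seed)
    ),
    class = "scatterer_dynamics"
  )
}

#' Full parameterization of the synthetic interferometer
#'
#' Bundles acquisition metadata, scatterer dynamics, the partial-coherence
#' gate and the camera noise model into one simulation specification. The
#' signal model is scalar and single-scatterer-per-pixel: each camera pixel
#' records
#' \deqn{I(t) = I_r + I_s + 2\sqrt{I_r I_s}\, V(\Delta(t)) \cos(\phi_0 + 4\pi\,\delta z(t)/\bar\lambda)}
#' where \eqn{V} is the Gaussian coherence envelope, \eqn{\Delta(t)} the
#' double-pass optical path mismatch (static map plus gate mismatch plus
#' \eqn{2\,\delta z(t)}) and \eqn{\delta z(t)} the axial scatterer
#' displacement. Poisson shot noise at photoelectron scale, full-well
#' clipping and digitizer quantization are optional final stages.
#'
#' @param meta An [acquisition_meta()].
#' @param dynamics A [scatterer_dynamics()].
#' @param reference_intensity Reference-arm return per pixel and frame,
#'   photoelectrons. The default, 10% of full well, mirrors a reference arm
#'   attenuated to 10% in the double pass to optimize SNR.
#' @param coherence_length_fwhm Coherence length (FWHM of the fringe
#'   envelope), nm. `NULL` derives it from the source spectrum in `meta` as
#'   \eqn{(2\ln 2/\pi)\,\bar\lambda^2/\Delta\lambda} (Gaussian spectrum),
#'   about 794 nm for the 600/200 nm default source.
#' @param path_mismatch Static double-pass path-mismatch map, nm (scalar or
#'   Y x X matrix); a residual tilt/defocus surrogate.
#' @param phase_offset Interferometric phase \eqn{\phi_0} (scalar or
#'   Y x X matrix), rad. The default pi/2 puts pixels at quadrature, where
#'   intensity is most sensitive to axial motion.
#' @param n_sample,n_immersion Sample and immersion refractive indices
#'   (both >= 1); their mismatch displaces the coherence gate from the
#'   focal plane as the stage moves (see [predicted_gate_slope()]).
#' @param stage_displacement Sample stage displacement toward the objective,
#'   micrometres.
#' @param reference_offset Reference-arm translation (positive lengthens the
#'   reference path), micrometres.
#' @param shot_noise Apply Poisson shot noise (photoelectron statistics)?
#' @param quantize Quantize output to `meta$bit_depth` digital numbers
#'   (full scale = full well)? When off, output stays in photoelectrons.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(meta = acquisition_meta(),
                            dynamics = scatterer_dynamics(),
                            reference_intensity = 0.1 * meta$full_well,
                            coherence_length_fwhm = NULL,
                            path_mismatch = 0,
                            phase_offset = pi / 2,
                            n_sample = 1.40,
                            n_immersion = 1.515,
                            stage_displacement = 0,
                            reference_offset = 0,
                            shot_noise = TRUE,
                            quantize = FALSE) {
  if (!inherits(meta, "acquisition_meta"))
    stop_parameter("meta must be an acquisition_meta object")
  if (!inherits(dynamics, "scatterer_dynamics"))
    stop_parameter("dynamics must be a scatterer_dynamics object")
  if (reference_intensity < 0)
    stop_parameter("reference_intensity must be >= 0")
  if (is.null(coherence_length_fwhm))
    coherence_length_fwhm <-
      (2 * log(2) / pi) * meta$center_wavelength^2 / meta$bandwidth_fwhm
  if (coherence_length_fwhm <= 0)
    stop_parameter("coherence_length_fwhm must be positive")
  if (n_sample < 1 || n_immersion < 1)
    stop_parameter("refractive indices must be >= 1")
  structure(
    list(
      meta = meta,
      dynamics = dynamics,
      reference_intensity = reference_intensity,
      coherence_length_fwhm = coherence_length_fwhm,
      path_mismatch = path_mismatch,
      phase_offset = phase_offset,
      n_sample = n_sample,
      n_immersion = n_immersion,
      stage_displacement = stage_displacement,
      reference_offset = reference_offset,
      shot_noise = isTRUE(shot_noise),
      quantize = isTRUE(quantize)
    ),
    class = "simulation_spec"
  )
}

#' Partial-coherence fringe envelope
#'
#' Fringe visibility of a broadband (Gaussian-spectrum) source as a function
#' of optical path mismatch: `V(delta) = exp(-4 ln2 delta^2 / l_c^2)`, a
#' Gaussian of FWHM `l_c` with `V(0) = 1`.
#'
#' @param path_mismatch Optical path mismatch, nm (any numeric shape).
#' @param coherence_length_fwhm Coherence length (envelope FWHM), nm; > 0.
#' @return Visibility values in `[0, 1]`, same shape as `path_mismatch`.
#' @examples
#' coherence_envelope(0, 800)    # 1
#' coherence_envelope(400, 800)  # 0.5, by the FWHM definition
#' @export
coherence_envelope <- function(path_mismatch, coherence_length_fwhm) {
  if (!is.numeric(coherence_length_fwhm) || length(coherence_length_fwhm) != 1 ||
      coherence_length_fwhm <= 0)
    stop_parameter("coherence_length_fwhm must be a single positive number")
  exp(-4 * log(2) * path_mismatch^2 / coherence_length_fwhm^2)
}

# Residual double-pass gate mismatch (nm) between the coherence gate and the
# focal plane for the current stage position and reference-arm offset.
gate_mismatch_nm <- function(spec) {
  slope <- (spec$n_sample^2 - spec$n_immersion^2) / spec$n_immersion
  2 * (spec$reference_offset - spec$stage_displacement * slope) * 1000
}

# Region labels actually used, in ascending order (0 = background excluded).
region_labels <- function(dynamics, meta) {
  if (is.null(dynamics$regions)) 1L
  else sort(unique(as.integer(dynamics$regions[dynamics$regions != 0])))
}

region_index_map <- function(dynamics, meta, labels) {
  if (is.null(dynamics$regions)) {
    rep(1L, meta$height * meta$width)
  } else {
    r <- dynamics$regions
    if (!identical(dim(r), c(meta$height, meta$width)))
      stop_structural("regions label map does not match the image shape")
    match(as.integer(r), labels)  # NA = background
  }
}

# T x R matrix of axial displacement (nm) per region. Band-noise draws come
# from the dynamics seed so the realization is identical with camera noise
# toggled on or off.
displacement_series <- function(dynamics, meta) {
  tt <- (seq_len(meta$n_frames) - 1) / meta$frame_rate
  labels <- region_labels(dynamics, meta)
  nyq <- nyquist_frequency(meta)
  dz <- matrix(0, meta$n_frames, length(labels))
  for (cmp in dynamics$components) {
    if (cmp$frequency >= nyq)
      stop_parameter("component frequency %g Hz is at or above Nyquist (%g Hz)",
                     cmp$frequency, nyq)
    j <- match(if (is.null(cmp$region)) 1L else as.integer(cmp$region), labels)
    if (is.na(j)) next
    ph <- if (is.null(cmp$phase)) 0 else cmp$phase
    dz[, j] <- dz[, j] +
      cmp$displacement_amplitude * sin(2 * pi * cmp$frequency * tt + ph)
  }
  if (!is.null(dynamics$band_noise)) {
    withr::with_seed(dynamics$seed, {
      for (bn in dynamics$band_noise) {
        if (bn$f_hi > nyq)
          stop_parameter("band_noise f_hi %g Hz exceeds Nyquist (%g Hz)",
                         bn$f_hi, nyq)
        targets <- if (is.null(bn$region)) seq_along(labels)
                   else match(as.integer(bn$region), labels)
        for (j in targets[!is.na(targets)]) {
          dz[, j] <- dz[, j] +
            band_limited_noise(meta$n_frames, meta$frame_rate,
                               bn$f_lo, bn$f_hi, bn$rms_displacement)
        }
      }
    })
  }
  dz
}

# White Gaussian series band-pass filtered in the Fourier domain and
# rescaled to the requested RMS.
band_limited_noise <- function(n, fs, f_lo, f_hi, rms) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * fs / n
  keep <- abs(freqs) >= f_lo & abs(freqs) <= f_hi
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- sqrt(mean(y^2))
  if (s == 0) rep(0, n) else y * rms / s
}

# Shared ideal-signal evaluation: returns a T x N matrix of noise-free
# photoelectron counts given per-frame displacements (T x R).
ideal_signal_matrix <- function(spec, dz) {
  meta <- spec$meta
  n_px <- meta$height * meta$width
  labels <- region_labels(spec$dynamics, meta)
  idx <- region_index_map(spec$dynamics, meta, labels)

  dzcols <- cbind(0, dz)                       # column 1 = static background
  col <- ifelse(is.na(idx), 1L, idx + 1L)
  DZ <- dzcols[, col, drop = FALSE]            # T x N displacement in nm

  refl <- spec$dynamics$static_reflectivity
  Is <- if (length(refl) == 1) rep(refl, n_px) else as.vector(refl)
  Is <- Is * spec$reference_intensity
  Ir <- spec$reference_intensity
  pm <- spec$path_mismatch
  pm <- if (length(pm) == 1) rep(pm, n_px) else as.vector(pm)
  ph0 <- spec$phase_offset
  ph0 <- if (length(ph0) == 1) rep(ph0, n_px) else as.vector(ph0)

  tN <- nrow(DZ)
  PM <- sweep(2 * DZ, 2, pm + gate_mismatch_nm(spec), "+")
  V <- coherence_envelope(PM, spec$coherence_length_fwhm)
  PH <- sweep(4 * pi * DZ / meta$center_wavelength, 2, ph0, "+")
  AMP <- matrix(2 * sqrt(Ir * Is), tN, n_px, byrow = TRUE)
  sweep(AMP * V * cos(PH), 2, Ir + Is, "+")
}

apply_camera <- function(I, spec, noise_seed) {
  meta <- spec$meta
  if (spec$shot_noise) {
    d <- dim(I)
    I <- withr::with_seed(noise_seed, as.numeric(stats::rpois(length(I), I)))
    dim(I) <- d
  }
  I <- pmin(pmax(I, 0), meta$full_well)
  if (spec$quantize)
    I <- round(I * (2^meta$bit_depth - 1) / meta$full_well)
  I
}

#' Simulate a raw interferogram time-stack
#'
#' Evaluates the scalar interference model frame by frame with the phase
#' actuator off: temporal intensity fluctuations arise solely from the
#' prescribed axial scatterer motion, as in dynamic-contrast acquisition.
#' Camera effects (Poisson shot noise, full-well clipping, quantization) are
#' applied per the spec. Dynamics and shot noise draw from independent,
#' seed-derived substreams, so the displacement realization is reproducible
#' with noise toggled on or off; a fixed spec yields bit-identical stacks.
#'
#' @param spec A [simulation_spec()].
#' @return A [raw_stack()].
#' @examples
#' spec <- simulation_spec(
#'   meta = acquisition_meta(n_frames = 64, height = 8, width = 8),
#'   dynamics = scatterer_dynamics(
#'     components = list(list(region = 1, frequency = 25,
#'                            displacement_amplitude = 20))),
#'   shot_noise = FALSE)
#' stk <- simulate_stack(spec)
#' @export
simulate_stack <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop_parameter("spec must be a simulation_spec object")
  meta <- spec$meta
  dz <- displacement_series(spec$dynamics, meta)
  I <- ideal_signal_matrix(spec, dz)
  I <- apply_camera(I, spec, noise_seed = spec$dynamics$seed + 1L)
  dim(I) <- c(meta$n_frames, meta$height, meta$width)
  raw_stack(I, meta)
}

#' Simulate four phase-stepped frames
#'
#' Freezes the scatterer dynamics at the first time point and images the
#' field four times with imposed interferometric phase offsets of 0, 90, 180
#' and 270 degrees (piezo phase stepping), the acquisition mode of
#' conventional static FF-OCM. The piezo step is treated as a pure phase
#' shift; its sub-wavelength stroke is negligible against the coherence
#' envelope.
#'
#' @param spec A [simulation_spec()].
#' @return A [phase_quad()].
#' @export
simulate_phase_quad <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop_parameter("spec must be a simulation_spec object")
  meta <- spec$meta
  # frozen dynamics: deterministic component value at t = 0, no band noise
  labels <- region_labels(spec$dynamics, meta)
  dz0 <- rep(0, length(labels))
  for (cmp in spec$dynamics$components) {
    j <- match(if (is.null(cmp$region)) 1L else as.integer(cmp$region), labels)
    if (is.na(j)) next
    ph <- if (is.null(cmp$phase)) 0 else cmp$phase
    dz0[j] <- dz0[j] + cmp$displacement_amplitude * sin(ph)
  }
  dz <- matrix(dz0, 4, length(labels), byrow = TRUE)

  # evaluate each step with the offset phase: I_k uses phi0 + (k-1) * pi/2
  spec_k <- spec
  out <- vector("list", 4)
  for (k in 1:4) {
    spec_k$phase_offset <- spec$phase_offset + (k - 1) * pi / 2
    I <- ideal_signal_matrix(spec_k, dz[1, , drop = FALSE])
    I <- apply_camera(I, spec, noise_seed = spec$dynamics$seed + 1L + k)
    out[[k]] <- matrix(I, meta$height, meta$width)
  }
  phase_quad(out[[1]], out[[2]], out[[3]], out[[4]], meta = meta)
}
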