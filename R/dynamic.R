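#' Per-pixel temporal standard deviation
#'
#' The scalar dynamic-contrast map: the sample standard deviation
#' (denominator `T - 1`) of each pixel's intensity time series. Static
#' pixels map to 0; the map is invariant to adding a temporal constant per
#' pixel.
#'
#' @param stack A [raw_stack()] with at least 2 frames.
#' @return A Y x X matrix of non-negative standard deviations.
#' @export
temporal_std <- function(stack) {
  if (!inherits(stack, "raw_stack"))
    stop_structural("stack must be a raw_stack object")
  m <- stack_matrix(stack)
  tN <- nrow(m)
  if (tN < 2)
    stop_degenerate("temporal STD needs at least 2 frames")
  mu <- colMeans(m)
  ss <- colSums(m^2) - tN * mu^2
  ss[ss < 0] <- 0   # guard against negative rounding residue
  matrix(sqrt(ss / (tN - 1)), stack$meta$height, stack$meta$width)
}

#' Per-pixel temporal fluctuation spectrum
#'
#' Pixel-by-pixel FFT of the intensity time series: a one-sided discrete
#' magnitude spectrum per pixel, rectangular window, no zero padding. The
#' scaling is chosen so that Parseval's identity holds in band-integrated
#' form: the sum of one-sided AC power (squared magnitudes over all bins
#' above DC) equals the population temporal variance of the pixel. A pure
#' unit-amplitude cosine at an interior bin therefore has magnitude
#' `1/sqrt(2)` (its RMS) in that bin. The DC bin is retained in the cube but
#' is never included in band integrals.
#'
#' @param stack A [raw_stack()] (normalized upstream) with at least 4 frames.
#' @return A `spectrum_cube`: list with `magnitudes` (F x Y x X), `freqs`
#'   (F ascending frequencies from 0 to Nyquist, spacing
#'   `frame_rate / n_frames`) and `meta`.
#' @export
pixel_spectrum <- function(stack) {
  if (!inherits(stack, "raw_stack"))
    stop_structural("stack must be a raw_stack object")
  m <- stack_matrix(stack)
  tN <- nrow(m)
  if (tN < 4)
    stop_degenerate("pixel_spectrum needs at least 4 frames")
  X <- stats::mvfft(m)
  n_half <- floor(tN / 2)
  keep <- seq_len(n_half + 1)              # DC .. Nyquist (or highest bin)
  mag <- Mod(X[keep, , drop = FALSE]) / tN
  # double interior bins (amplitude scale: sqrt(2) on magnitude)
  interior <- keep > 1 & (keep - 1) < tN / 2
  mag[interior, ] <- mag[interior, ] * sqrt(2)
  freqs <- (keep - 1) * stack$meta$frame_rate / tN
  dim(mag) <- c(length(keep), stack$meta$height, stack$meta$width)
  structure(list(magnitudes = mag, freqs = freqs, meta = stack$meta),
            class = "spectrum_cube")
}

#' @export
print.spectrum_cube <- function(x, ...) {
  d <- dim(x$magnitudes)
  cat(sprintf("<spectrum_cube> %d bins (0-%g Hz, step %g Hz) x %dx%d px\n",
              d[1], max(x$freqs), x$freqs[2] - x$freqs[1], d[2], d[3]))
  invisible(x)
}

# Logical selector of cube bins falling in [lo, hi); the DC bin is always
# excluded, and a band whose upper edge equals Nyquist includes it so that
# bands tiling (0, nyquist] cover every AC bin.
band_bin_mask <- function(freqs, lo, hi, nyquist) {
  sel <- freqs >= lo & freqs < hi
  if (isTRUE(all.equal(hi, nyquist))) sel <- sel | freqs == nyquist
  sel & freqs > 0
}

#' Integrate a fluctuation spectrum into three frequency bands
#'
#' Sums the chosen spectral quantity (magnitude or power) over the bins of
#' each band of a [band_definition()], producing the three per-pixel maps
#' that become the blue (low), green (mid) and red (high) channels. Bin
#' membership is by bin-centre frequency in the half-open interval
#' `[lo, hi)`; the DC bin is never included. A band containing no bins
#' yields a zero map with a warning.
#'
#' @param cube A `spectrum_cube` from [pixel_spectrum()].
#' @param bands A [band_definition()].
#' @param quantity `"magnitude"` or `"power"`.
#' @return Named list of three Y x X maps: `low`, `mid`, `high`.
#' @export
integrate_bands <- function(cube, bands = band_definition(),
                            quantity = c("magnitude", "power")) {
  if (!inherits(cube, "spectrum_cube"))
    stop_structural("cube must be a spectrum_cube object")
  quantity <- match.arg(quantity)
  nyq <- nyquist_frequency(cube$meta)
  validate_bands(bands, nyq)
  vals <- cube$magnitudes
  if (quantity == "power") vals <- vals^2
  d <- dim(vals)
  dim(vals) <- c(d[1], d[2] * d[3])
  out <- lapply(rownames(bands), function(nm) {
    sel <- band_bin_mask(cube$freqs, bands[nm, "lo"], bands[nm, "hi"], nyq)
    if (!any(sel)) {
      warn_dffocm("band %s (%g-%g Hz) contains no spectral bins", nm,
                  bands[nm, "lo"], bands[nm, "hi"])
      return(matrix(0, d[2], d[3]))
    }
    matrix(colSums(vals[sel, , drop = FALSE]), d[2], d[3])
  })
  names(out) <- rownames(bands)
  out
}

#' Mean fluctuation spectrum over the field of view
#'
#' Arithmetic mean of all per-pixel spectra, bin by bin: the image-average
#' fluctuation spectrum.
#'
#' @param cube A `spectrum_cube`.
#' @return Data frame with columns `freq` (Hz) and `magnitude`.
#' @export
mean_spectrum <- function(cube) {
  if (!inherits(cube, "spectrum_cube"))
    stop_structural("cube must be a spectrum_cube object")
  d <- dim(cube$magnitudes)
  m <- cube$magnitudes
  dim(m) <- c(d[1], d[2] * d[3])
  data.frame(freq = cube$freqs, magnitude = rowMeans(m))
}

# log10 with the additive epsilon from the render config (default 1e-12 of
# the channel maximum, floored at 1e-30, so log is defined at zero).
log_stretch_channel <- function(v, cfg) {
  eps <- cfg$log_epsilon
  if (is.null(eps)) eps <- max(max(v) * 1e-12, 1e-30)
  lv <- log10(v + eps)
  lo <- stats::quantile(lv, cfg$zero_low_percent / 100, names = FALSE, type = 7)
  hi <- stats::quantile(lv, 1 - cfg$saturate_high_percent / 100,
                        names = FALSE, type = 7)
  if (hi <= lo) {
    warn_dffocm("channel has no dynamic range after the log transform; rendered all-zero")
    return(array(0, dim(v)))
  }
  out <- (lv - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Assemble band maps into an RGB composite
#'
#' Log-transforms each integrated band map (`log10(v + eps)`), clips each
#' channel at its lower `zero_low_percent` and upper
#' `100 - saturate_high_percent` percentiles (linear-interpolation
#' percentiles over all pixels) and rescales affinely to `[0, 1]`. Values at
#' or above the upper percentile render exactly 1; at or below the lower
#' percentile, exactly 0. The high band becomes red, mid green, low blue.
#'
#' @param band_maps Named list `low`, `mid`, `high` of non-negative maps of
#'   one shape, as returned by [integrate_bands()].
#' @param cfg A [render_config()].
#' @return A 3 x Y x X array in `[0, 1]`, channels ordered R, G, B.
#' @export
render_rgb <- function(band_maps, cfg = render_config()) {
  if (!all(c("low", "mid", "high") %in% names(band_maps)))
    stop_structural("band_maps must contain maps named low, mid and high")
  d <- dim(band_maps$low)
  if (!identical(dim(band_maps$mid), d) || !identical(dim(band_maps$high), d))
    stop_structural("band maps must share one shape")
  if (any(vapply(band_maps, function(m) any(m < 0), logical(1))))
    stop_structural("band maps must be non-negative")
  rgb <- array(0, c(3, d[1], d[2]))
  rgb[1, , ] <- log_stretch_channel(band_maps$high, cfg)  # red   = fast
  rgb[2, , ] <- log_stretch_channel(band_maps$mid, cfg)   # green = mid
  rgb[3, , ] <- log_stretch_channel(band_maps$low, cfg)   # blue  = slow
  rgb
}

#' Full dynamic-contrast pipeline
#'
#' The complete per-stack processing chain: flicker normalization,
#' pixel-by-pixel FFT, three-band integration, log transform and percentile
#' stretch into an RGB composite, plus the temporal-STD map. Deterministic
#' for a fixed input stack.
#'
#' @param stack A [raw_stack()].
#' @param bands A [band_definition()].
#' @param cfg A [render_config()].
#' @param normalize Apply [normalize_stack()] first (default `TRUE`)?
#' @param response_correction Passed to [normalize_stack()].
#' @return A `dynamic_image`: list with `rgb` (3 x Y x X in `[0, 1]`,
#'   channels R, G, B), `std_map` (Y x X), `band_maps` (raw pre-render
#'   integrals), `bands`, `cfg` and `meta`.
#' @examples
#' spec <- simulation_spec(
#'   meta = acquisition_meta(n_frames = 128, height = 8, width = 8),
#'   dynamics = scatterer_dynamics(
#'     components = list(list(region = 1, frequency = 50,
#'                            displacement_amplitude = 20))),
#'   shot_noise = FALSE)
#' img <- dynamic_pipeline(simulate_stack(spec))
#' dim(img$rgb)
#' @export
dynamic_pipeline <- function(stack, bands = band_definition(),
                             cfg = render_config(), normalize = TRUE,
                             response_correction = NULL) {
  if (normalize)
    stack <- normalize_stack(stack, response_correction)
  std_map <- temporal_std(stack)
  cube <- pixel_spectrum(stack)
  band_maps <- integrate_bands(cube, bands, quantity = cfg$spectrum_quantity)
  rgb <- if (all(std_map == 0)) {
    # static stack: no fluctuation signal anywhere, render black without
    # percentile warnings
    array(0, c(3, dim(std_map)))
  } else {
    render_rgb(band_maps, cfg)
  }
  structure(
    list(rgb = rgb, std_map = std_map, band_maps = band_maps,
         bands = bands, cfg = cfg, meta = stack$meta),
    class = "dynamic_image"
  )
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$std_map)
  cat(sprintf("<dynamic_image> %dx%d px, mean STD %.3g, channel means R %.3f G %.3f B %.3f\n",
              d[1], d[2], mean(x$std_map),
              mean(x$rgb[1, , ]), mean(x$rgb[2, , ]), mean(x$rgb[3, , ])))
  invisible(x)
}

#' Assemble dynamic images into a volume with orthogonal projections
#'
#' Stacks en-face dynamic images acquired at successive depths into an RGB
#' volume and computes per-channel maximum-intensity projections along each
#' axis.
#'
#' @param images List of `dynamic_image` objects of one shape, ordered by
#'   increasing depth.
#' @param z_step Axial step between images, micrometres.
#' @return List with `volume` (3 x Z x Y x X), `z_step` and projections
#'   `xy` (3 x Y x X), `xz` (3 x Z x X), `yz` (3 x Z x Y).
#' @export
assemble_volume <- function(images, z_step = 1) {
  if (length(images) < 1)
    stop_structural("need at least one dynamic image")
  if (z_step <= 0)
    stop_parameter("z_step must be positive")
  dims <- lapply(images, function(im) dim(im$rgb))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_structural("all dynamic images must share one shape")
  d <- dims[[1]]
  nz <- length(images)
  vol <- array(0, c(3, nz, d[2], d[3]))
  for (i in seq_len(nz)) vol[, i, , ] <- images[[i]]$rgb
  list(
    volume = vol,
    z_step = z_step,
    xy = apply(vol, c(1, 3, 4), max),
    xz = apply(vol, c(1, 2, 4), max),
    yz = apply(vol, c(1, 2, 3), max)
  )
}
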