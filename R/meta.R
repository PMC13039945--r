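#' Acquisition metadata
#'
#' Describes one camera time-stack acquisition: frame rate, stack length,
#' image geometry, source spectrum and camera characteristics. Defaults
#' mirror the reference instrument: 500 frames/s, 512-frame stacks, 120 nm
#' pixel pitch in the sample plane, a white-light source centred at 600 nm
#' with 200 nm FWHM bandwidth (the visible spectrum above a 490 nm cut-on
#' filter), and a high full-well-capacity camera holding 2e6 photoelectrons
#' per pixel.
#'
#' @param frame_rate Frames per second (Hz). Must be positive.
#' @param n_frames Number of frames in a stack. Must be at least 2.
#' @param height,width Image dimensions in pixels.
#' @param pixel_pitch Pixel size in the sample plane, nanometres.
#' @param center_wavelength Source centre wavelength, nanometres.
#' @param bandwidth_fwhm Source spectral bandwidth (FWHM), nanometres; must
#'   be smaller than the centre wavelength.
#' @param full_well Camera full-well capacity, photoelectrons.
#' @param bit_depth Camera digitizer depth, bits (used only when stacks are
#'   quantized).
#'
#' @return An object of class `acquisition_meta`.
#' @examples
#' meta <- acquisition_meta(height = 32, width = 32)
#' nyquist_frequency(meta)
#' @export
acquisition_meta <- function(frame_rate = 500,
                             n_frames = 512,
                             height = 64,
                             width = 64,
                             pixel_pitch = 120,
                             center_wavelength = 600,
                             bandwidth_fwhm = 200,
                             full_well = 2e6,
                             bit_depth = 12) {
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop_parameter("frame_rate must be a single positive number")
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 2)
    stop_parameter("n_frames must be at least 2")
  if (height < 1 || width < 1)
    stop_parameter("height and width must be positive")
  if (pixel_pitch <= 0)
    stop_parameter("pixel_pitch must be positive")
  if (bandwidth_fwhm <= 0 || bandwidth_fwhm >= center_wavelength)
    stop_parameter("bandwidth_fwhm must lie in (0, center_wavelength)")
  if (full_well <= 0)
    stop_parameter("full_well must be positive")
  if (bit_depth < 1 || bit_depth > 32)
    stop_parameter("bit_depth must be between 1 and 32")
  structure(
    list(
      frame_rate = as.numeric(frame_rate),
      n_frames = as.integer(n_frames),
      height = as.integer(height),
      width = as.integer(width),
      pixel_pitch = as.numeric(pixel_pitch),
      center_wavelength = as.numeric(center_wavelength),
      bandwidth_fwhm = as.numeric(bandwidth_fwhm),
      full_well = as.numeric(full_well),
      bit_depth = as.integer(bit_depth)
    ),
    class = "acquisition_meta"
  )
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf(
    "<acquisition_meta> %d frames %dx%d px @ %g fps, pitch %g nm, lambda %g+/-%g nm, FWC %g e-\n",
    x$n_frames, x$height, x$width, x$frame_rate, x$pixel_pitch,
    x$center_wavelength, x$bandwidth_fwhm / 2, x$full_well
  ))
  invisible(x)
}

#' Nyquist frequency of an acquisition
#'
#' Half the frame rate: the highest temporal fluctuation frequency the
#' per-pixel spectrum can represent.
#'
#' @param meta An [acquisition_meta()] object.
#' @return Frequency in Hz.
#' @export
nyquist_frequency <- function(meta) {
  meta$frame_rate / 2
}

as_meta_list <- function(meta) {
  unclass(meta)
}

meta_from_list <- function(x) {
  do.call(acquisition_meta, x[names(x) %in% names(formals(acquisition_meta))])
}
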