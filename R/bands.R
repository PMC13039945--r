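#' Three-band frequency definition for RGB encoding
#'
#' Defines the low, mid and high temporal-frequency intervals that are
#' mapped to the blue, green and red channels of the dynamic image. The
#' defaults (1-3, 3-100, 100-250 Hz) emphasise slow, intermediate and fast
#' subcellular motions at a 500 Hz frame rate; the edges are deliberately
#' tunable because the rendered image is fairly stable under moderate
#' changes of binning.
#'
#' Intervals are half-open `[lo, hi)`: a spectral bin whose centre
#' frequency equals a shared edge belongs to the upper band. As the single
#' exception, a band whose upper edge equals the Nyquist frequency includes
#' it, so that bands tiling `(0, nyquist]` partition all AC bins.
#'
#' @param edges Numeric vector of four ascending positive band edges in Hz:
#'   `c(low_lo, low_hi = mid_lo, mid_hi = high_lo, high_hi)`.
#' @return An object of class `band_definition`: a 3 x 2 matrix of
#'   `[lo, hi)` edges with rows `low`, `mid`, `high`.
#' @examples
#' band_definition()              # 1-3, 3-100, 100-250 Hz
#' band_definition(c(1, 2, 100, 250))
#' @export
band_definition <- function(edges = c(1, 3, 100, 250)) {
  if (length(edges) != 4 || !is.numeric(edges))
    stop_parameter("edges must be four numbers: low_lo, low_hi, mid_hi, high_hi")
  if (any(diff(edges) <= 0))
    stop_parameter("band edges must be strictly ascending")
  if (edges[1] <= 0)
    stop_parameter("the lowest band edge must be positive (the DC bin is never integrated)")
  m <- cbind(lo = edges[1:3], hi = edges[2:4])
  rownames(m) <- c("low", "mid", "high")
  structure(m, class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band_definition> blue %g-%g Hz, green %g-%g Hz, red %g-%g Hz\n",
              x[1, 1], x[1, 2], x[2, 1], x[2, 2], x[3, 1], x[3, 2]))
  invisible(x)
}

validate_bands <- function(bands, nyquist) {
  if (!inherits(bands, "band_definition"))
    stop_parameter("bands must be a band_definition object")
  if (bands[3, 2] > nyquist + 1e-9)
    stop_parameter("highest band edge %g Hz exceeds the Nyquist frequency %g Hz",
                   bands[3, 2], nyquist)
  invisible(bands)
}

#' Rendering configuration for the RGB composite
#'
#' Controls the log transform and percentile contrast stretch applied to the
#' three integrated band maps before they are assembled into an RGB image.
#' By default the highest 1% of values in each channel are saturated to full
#' intensity and the lowest 1% are set to zero.
#'
#' @param saturate_high_percent Percentage of top values clipped to 1 per
#'   channel (default 1).
#' @param zero_low_percent Percentage of bottom values clipped to 0 per
#'   channel (default 1).
#' @param log_epsilon Additive offset inside the log10, defining the
#'   transform at zero. `NULL` (default) uses 1e-12 of the channel maximum
#'   with an absolute floor of 1e-30.
#' @param spectrum_quantity Spectral quantity integrated over each band:
#'   `"magnitude"` (default, amplitude-spectrum integration) or `"power"`
#'   (squared magnitudes; the quantity conserved by Parseval's theorem).
#' @return An object of class `render_config`.
#' @export
render_config <- function(saturate_high_percent = 1,
                          zero_low_percent = 1,
                          log_epsilon = NULL,
                          spectrum_quantity = c("magnitude", "power")) {
  if (saturate_high_percent < 0 || saturate_high_percent >= 50)
    stop_parameter("saturate_high_percent must lie in [0, 50)")
  if (zero_low_percent < 0 || zero_low_percent >= 50)
    stop_parameter("zero_low_percent must lie in [0, 50)")
  if (!is.null(log_epsilon) && (!is.numeric(log_epsilon) || log_epsilon <= 0))
    stop_parameter("log_epsilon must be a positive number or NULL")
  structure(
    list(
      saturate_high_percent = saturate_high_percent,
      zero_low_percent = zero_low_percent,
      log_epsilon = log_epsilon,
      spectrum_quantity = match.arg(spectrum_quantity)
    ),
    class = "render_config"
  )
}
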