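#' Normalize a raw stack against source flicker
#'
#' Corrects multiplicative frame-to-frame gain variations (light-source
#' flicker) before temporal analysis: each frame is divided by its spatial
#' mean and multiplied by the grand mean of all frame means, so per-frame
#' means are equalized while the stack's global mean is preserved. Camera
#' nonlinearity can be undone first by a caller-supplied monotone response
#' map (measured value to linearized value); the default is the identity.
#'
#' The operation is idempotent and removes pure flicker exactly: a stack
#' whose frames are `g_t * F` for a fixed image `F` comes out as
#' `mean(g) * F` in every frame.
#'
#' @param stack A [raw_stack()] with at least 2 frames, every frame having a
#'   positive spatial mean.
#' @param response_correction Optional camera response correction: a
#'   monotone function, or a two-column matrix/data.frame LUT
#'   (measured, linearized) interpolated linearly and extrapolated by its
#'   end rule.
#' @return A normalized [raw_stack()].
#' @examples
#' meta <- acquisition_meta(n_frames = 3, height = 2, width = 2)
#' f <- array(rep(c(0.9, 1, 1.1), 4) * 100, c(3, 2, 2))
#' normalize_stack(raw_stack(f, meta))  # every frame constant 100
#' @export
normalize_stack <- function(stack, response_correction = NULL) {
  if (!inherits(stack, "raw_stack"))
    stop_structural("stack must be a raw_stack object")
  frames <- stack$frames
  d <- dim(frames)
  if (d[1] < 2)
    stop_degenerate("normalization needs at least 2 frames")

  if (!is.null(response_correction)) {
    fun <- response_fun(response_correction)
    frames <- array(fun(frames), d)
    if (any(!is.finite(frames)))
      stop_numerical("response correction produced non-finite values")
  }

  m <- matrix(frames, d[1], d[2] * d[3])
  frame_means <- rowMeans(m)
  if (any(frame_means <= 0))
    stop_degenerate("every frame must have a positive spatial mean")
  grand <- mean(frame_means)
  m <- m * (grand / frame_means)   # row-wise gain correction
  dim(m) <- d
  raw_stack(m, stack$meta)
}

response_fun <- function(response_correction) {
  if (is.function(response_correction)) return(response_correction)
  lut <- as.matrix(response_correction)
  if (ncol(lut) != 2 || nrow(lut) < 2)
    stop_parameter("response LUT must have two columns and at least two rows")
  if (any(diff(lut[, 1]) <= 0))
    stop_parameter("response LUT measured values must be strictly increasing")
  if (any(diff(lut[, 2]) < 0))
    stop_parameter("response LUT must be monotone non-decreasing")
  stats::approxfun(lut[, 1], lut[, 2], rule = 2)
}
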