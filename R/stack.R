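#' Raw camera time-stack
#'
#' The pipeline's universal input: a T x Y x X array of non-negative
#' camera intensities together with its [acquisition_meta()].
#'
#' @param frames Numeric T x Y x X array; all values finite and >= 0.
#' @param meta An [acquisition_meta()]; `meta$n_frames` must equal `dim(frames)[1]`.
#' @return An object of class `raw_stack` with elements `frames` and `meta`.
#' @export
raw_stack <- function(frames, meta) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop_structural("frames must be a T x Y x X array")
  if (!inherits(meta, "acquisition_meta"))
    stop_structural("meta must be an acquisition_meta object")
  d <- dim(frames)
  if (d[1] != meta$n_frames)
    stop_structural("stack has %d frames but meta says %d", d[1], meta$n_frames)
  if (d[2] != meta$height || d[3] != meta$width)
    stop_structural("stack is %dx%d px but meta says %dx%d",
                    d[2], d[3], meta$height, meta$width)
  if (anyNA(frames) || any(!is.finite(frames)))
    stop_structural("stack contains non-finite values")
  if (any(frames < 0))
    stop_structural("stack contains negative intensities")
  structure(list(frames = frames, meta = meta), class = "raw_stack")
}

#' @export
print.raw_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<raw_stack> %d frames of %dx%d px @ %g fps, range [%g, %g]\n",
              d[1], d[2], d[3], x$meta$frame_rate,
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Four phase-stepped interferogram frames
#'
#' Container for the four frames acquired at 0, 90, 180 and 270 degree
#' piezo phase steps, the input of [reconstruct_static()].
#'
#' @param I1,I2,I3,I4 Y x X matrices of non-negative intensities at
#'   0, 90, 180 and 270 degrees respectively.
#' @param meta Optional [acquisition_meta()].
#' @return An object of class `phase_quad`.
#' @export
phase_quad <- function(I1, I2, I3, I4, meta = NULL) {
  frames <- list(I1 = I1, I2 = I2, I3 = I3, I4 = I4)
  d <- dim(I1)
  if (is.null(d) || length(d) != 2)
    stop_structural("phase frames must be matrices")
  for (nm in names(frames)) {
    f <- frames[[nm]]
    if (!identical(dim(f), d))
      stop_structural("frame %s does not match the shape of I1", nm)
    if (anyNA(f) || any(!is.finite(f)) || any(f < 0))
      stop_structural("frame %s contains negative or non-finite values", nm)
  }
  structure(c(frames, list(meta = meta)), class = "phase_quad")
}

#' @export
print.phase_quad <- function(x, ...) {
  d <- dim(x$I1)
  cat(sprintf("<phase_quad> 4 frames of %dx%d px\n", d[1], d[2]))
  invisible(x)
}

# T x (Y*X) pixel-major view of the stack; columns are per-pixel time series.
stack_matrix <- function(stack) {
  f <- stack$frames
  d <- dim(f)
  dim(f) <- c(d[1], d[2] * d[3])
  f
}
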