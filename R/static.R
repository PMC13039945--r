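#' Static FF-OCM amplitude reconstruction
#'
#' Four-step phase-shifting demodulation: the conventional FF-OCM image is
#' \deqn{A = \sqrt{(I_1 - I_3)^2 + (I_2 - I_4)^2}}
#' computed pixelwise from frames acquired at 0, 90, 180 and 270 degree
#' phase steps. For an ideal quad \eqn{I_k = A_0 + B \cos(\phi_0 + k\pi/2)}
#' the result is exactly `2B`, independent of the incoherent background
#' \eqn{A_0} and of the interferometric phase \eqn{\phi_0}. No dark-frame
#' subtraction or normalization is applied here; callers normalize first if
#' needed.
#'
#' @param quad A [phase_quad()].
#' @return An `amplitude_image`: list with `values` (Y x X, >= 0) and `meta`.
#' @examples
#' q <- phase_quad(matrix(11, 2, 2), matrix(10, 2, 2),
#'                 matrix(9, 2, 2), matrix(10, 2, 2))
#' reconstruct_static(q)$values  # 2 everywhere (fringe amplitude B = 1)
#' @export
reconstruct_static <- function(quad) {
  if (!inherits(quad, "phase_quad"))
    stop_structural("quad must be a phase_quad object")
  values <- sqrt((quad$I1 - quad$I3)^2 + (quad$I2 - quad$I4)^2)
  structure(list(values = values, meta = quad$meta), class = "amplitude_image")
}

#' @export
print.amplitude_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<amplitude_image> %dx%d px, range [%g, %g]\n",
              d[1], d[2], min(x$values), max(x$values)))
  invisible(x)
}
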