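#' Predicted coherence-gate compensation slope
#'
#' When the sample stage moves the tissue a distance `dz` toward the
#' objective through an immersion medium of index `n_imm`, the geometric
#' focus lands at depth `dz * n_s / n_imm` inside a sample of index `n_s`
#' (paraxial model). Keeping the coherence gate on the focal plane then
#' requires a single-pass reference-arm path change of
#' `dz * (n_s^2 - n_imm^2) / n_imm`. This function returns that slope in
#' micrometres of reference translation per micrometre of stage
#' displacement. Matched indices need no compensation; for tissue under oil
#' immersion (`n_s < n_imm`) the slope is negative, i.e. the reference path
#' must shorten.
#'
#' @param n_sample,n_immersion Refractive indices, both >= 1.
#' @return Slope, micrometre per micrometre.
#' @examples
#' predicted_gate_slope(1.40, 1.515)  # -0.2213 for tissue in oil
#' @export
predicted_gate_slope <- function(n_sample, n_immersion) {
  if (any(n_sample < 1) || any(n_immersion < 1))
    stop_parameter("refractive indices must be >= 1")
  (n_sample^2 - n_immersion^2) / n_immersion
}

#' Calibrate the gate compensation slope on the simulator
#'
#' Emulates the instrument calibration routine: displace the sample stage a
#' known distance (default 30 micrometres), then sweep the reference-arm
#' offset over a grid, simulating a phase-stepped quad and scoring each
#' offset by the mean static fringe amplitude (image contrast). The optimum
#' offset maximizes contrast; the calibration slope is
#' `optimum_offset / displacement` and recovers [predicted_gate_slope()]
#' within one grid step.
#'
#' @param spec A [simulation_spec()]; its refractive indices define the
#'   mismatch being calibrated. Shot noise is disabled during the sweep.
#' @param displacement Stage displacement used for calibration, micrometres.
#' @param offsets Grid of candidate reference-arm offsets, micrometres; must
#'   span the predicted optimum. Default: predicted optimum +/- 2 um in
#'   0.1 um steps.
#' @return A `gate_calibration`: list with `contrast_curve` (data frame of
#'   `reference_offset`, `contrast`), `optimum_offset`, `slope`,
#'   `displacement` and `predicted_slope`.
#' @examples
#' spec <- simulation_spec(meta = acquisition_meta(height = 8, width = 8),
#'                         n_sample = 1.40, n_immersion = 1.515)
#' cal <- calibrate_gate(spec, displacement = 30,
#'                       offsets = seq(-8, -5, by = 0.25))
#' cal$slope
#' @export
calibrate_gate <- function(spec, displacement = 30, offsets = NULL) {
  if (!inherits(spec, "simulation_spec"))
    stop_parameter("spec must be a simulation_spec object")
  if (displacement <= 0)
    stop_parameter("displacement must be positive")
  predicted <- predicted_gate_slope(spec$n_sample, spec$n_immersion)
  if (is.null(offsets)) {
    center <- predicted * displacement
    offsets <- seq(center - 2, center + 2, by = 0.1)
  }
  if (length(offsets) < 3)
    stop_parameter("offset grid needs at least 3 points")
  offsets <- sort(offsets)

  spec$shot_noise <- FALSE
  spec$stage_displacement <- displacement
  contrast <- vapply(offsets, function(off) {
    spec$reference_offset <- off
    mean(reconstruct_static(simulate_phase_quad(spec))$values)
  }, numeric(1))

  i_opt <- which.max(contrast)
  if (i_opt == 1 || i_opt == length(offsets))
    warn_dffocm("contrast optimum lies on the grid boundary; widen the offset grid")
  optimum <- offsets[i_opt]
  structure(
    list(
      contrast_curve = data.frame(reference_offset = offsets,
                                  contrast = contrast),
      optimum_offset = optimum,
      slope = optimum / displacement,
      displacement = displacement,
      predicted_slope = predicted
    ),
    class = "gate_calibration"
  )
}

#' @export
print.gate_calibration <- function(x, ...) {
  cat(sprintf(
    "<gate_calibration> optimum offset %.3f um over %.1f um -> slope %.4f (model %.4f)\n",
    x$optimum_offset, x$displacement, x$slope, x$predicted_slope))
  invisible(x)
}
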