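#' Generate a deterministic test fixture on disk
#'
#' Produces small simulated datasets with known ground truth, used by the
#' test suite and handy for demos. Every preset is a pure function of
#' `(name, seed)`: rerunning writes byte-identical files. Each preset
#' writes a `<name>-manifest.json` describing the files and the ground
#' truth they encode.
#'
#' Presets:
#' \describe{
#'   \item{`three-band-regions`}{A 512-frame 64 x 64 stack at 500 fps with
#'     three vertical regions driven at 2, 20 and 200 Hz (one per RGB
#'     band), shot noise on. Writes the stack, its sidecar, the region
#'     label mask and the manifest with per-region drive frequencies.}
#'   \item{`static-sample`}{A 128-frame 32 x 32 noise-free stack of a
#'     static sample: the dynamic pipeline must render it black.}
#'   \item{`gate-mismatch`}{Runs the gate calibration sweep for tissue
#'     (n = 1.40) under oil (n = 1.515) and writes the contrast curve as
#'     CSV plus the manifest with the predicted and recovered slope.}
#'   \item{`frc-cutoff`}{Two 128 x 128 images sharing band-limited
#'     structure with a 0.25 cycles/pixel cutoff plus independent noise,
#'     written as a 2-page TIFF; the manifest records the cutoff.}
#' }
#'
#' @param name Preset id.
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, invisibly (also stored in the
#'   manifest).
#' @export
make_fixture <- function(name = c("three-band-regions", "static-sample",
                                  "gate-mismatch", "frc-cutoff"),
                         seed = 1L, dir = ".") {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  manifest <- list(preset = name, seed = as.integer(seed))

  files <- switch(name,
    "three-band-regions" = {
      meta <- acquisition_meta(n_frames = 512, height = 64, width = 64)
      regions <- matrix(0L, 64, 64)
      regions[, 1:21] <- 1L
      regions[, 22:42] <- 2L
      regions[, 43:64] <- 3L
      freqs <- c(2, 20, 200)
      dyn <- scatterer_dynamics(
        static_reflectivity = 0.05,
        regions = regions,
        components = lapply(1:3, function(i)
          list(region = i, frequency = freqs[i], displacement_amplitude = 30)),
        seed = seed
      )
      spec <- simulation_spec(meta = meta, dynamics = dyn, shot_noise = TRUE)
      stk <- simulate_stack(spec)
      write_stack(stk, p("three-band-regions.tif"))
      write_label_mask(regions, p("three-band-regions-labels.tif"))
      manifest$regions <- lapply(1:3, function(i)
        list(label = i, frequency_hz = freqs[i], displacement_nm = 30,
             expected_channel = c("blue", "green", "red")[i]))
      list(stack = p("three-band-regions.tif"),
           sidecar = sidecar_path(p("three-band-regions.tif")),
           labels = p("three-band-regions-labels.tif"))
    },
    "static-sample" = {
      meta <- acquisition_meta(n_frames = 128, height = 32, width = 32)
      dyn <- scatterer_dynamics(static_reflectivity = 0.05, seed = seed)
      spec <- simulation_spec(meta = meta, dynamics = dyn, shot_noise = FALSE)
      stk <- simulate_stack(spec)
      write_stack(stk, p("static-sample.tif"))
      list(stack = p("static-sample.tif"),
           sidecar = sidecar_path(p("static-sample.tif")))
    },
    "gate-mismatch" = {
      meta <- acquisition_meta(n_frames = 4, height = 16, width = 16)
      dyn <- scatterer_dynamics(static_reflectivity = 0.05, seed = seed)
      spec <- simulation_spec(meta = meta, dynamics = dyn,
                              n_sample = 1.40, n_immersion = 1.515,
                              shot_noise = FALSE)
      cal <- calibrate_gate(spec, displacement = 30)
      utils::write.csv(cal$contrast_curve, p("gate-mismatch-curve.csv"),
                       row.names = FALSE)
      manifest$predicted_slope <- cal$predicted_slope
      manifest$recovered_slope <- cal$slope
      manifest$optimum_offset_um <- cal$optimum_offset
      list(curve = p("gate-mismatch-curve.csv"))
    },
    "frc-cutoff" = {
      cutoff <- 0.25
      imgs <- withr::with_seed(seed, {
        n <- 128
        structure_img <- lowpass_noise_image(n, cutoff)
        lapply(1:2, function(i) structure_img + 0.1 * matrix(stats::rnorm(n * n), n))
      })
      write_float_pages(imgs, p("frc-cutoff.tif"))
      manifest$cutoff_cycles_per_pixel <- cutoff
      list(pair = p("frc-cutoff.tif"))
    }
  )

  manifest$files <- files
  jsonlite::write_json(manifest, p(paste0(name, "-manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

# White Gaussian image low-pass filtered at a sharp radial cutoff
# (cycles/pixel) in the Fourier domain, unit variance.
lowpass_noise_image <- function(n, cutoff) {
  x <- matrix(stats::rnorm(n * n), n)
  X <- stats::fft(x)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  kx <- matrix(k, n, n)
  r <- sqrt(kx^2 + t(kx)^2)
  X[r > cutoff] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / (n * n)
  y / stats::sd(y)
}
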