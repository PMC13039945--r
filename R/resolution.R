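#' Fourier ring correlation between two images
#'
#' Normalized cross-correlation of two images' discrete spectra over rings
#' of spatial frequency,
#' \deqn{FRC(r) = \mathrm{Re}\left(\sum_r F_a \bar F_b\right) /
#'   \sqrt{\sum_r |F_a|^2 \sum_r |F_b|^2},}
#' used to estimate image resolution from two independent observations of
#' the same scene. Images are mean-subtracted internally; rings are defined
#' on the integer radius of the centred discrete spectrum, one frequency bin
#' wide. The resolution estimate is `pixel_pitch / f*`, where `f*` is the
#' first crossing of the FRC below the threshold curve (linear interpolation
#' between rings). If the FRC never crosses the threshold the resolution is
#' beyond the Nyquist limit of the sampling and is reported as `NA` with
#' `beyond_nyquist = TRUE`.
#'
#' @param image_a,image_b Equal-shape square matrices.
#' @param criterion Threshold criterion: `"fixed-1/7"` (constant 1/7) or
#'   `"half-bit"` (ring-population-dependent half-bit curve).
#' @param pixel_pitch Pixel size, nm (default 1: resolution in pixels).
#' @return An `frc_curve`: list with `ring_freqs` (cycles/pixel),
#'   `correlation`, `threshold`, `n_ring` (pixels per ring),
#'   `resolution_estimate` (same units as `pixel_pitch`), `crossing_freq`
#'   and `beyond_nyquist`.
#' @examples
#' set.seed(1)
#' img <- matrix(rnorm(64 * 64), 64)
#' frc(img, img)$correlation[1:5]  # identically 1: self-correlation
#' @export
frc <- function(image_a, image_b, criterion = c("fixed-1/7", "half-bit"),
                pixel_pitch = 1) {
  criterion <- match.arg(criterion)
  if (!is.matrix(image_a) || !is.matrix(image_b))
    stop_structural("images must be matrices")
  if (!identical(dim(image_a), dim(image_b)))
    stop_structural("images must share one shape")
  n <- nrow(image_a)
  if (ncol(image_a) != n)
    stop_structural("FRC requires square images")
  if (pixel_pitch <= 0)
    stop_parameter("pixel_pitch must be positive")

  Fa <- stats::fft(image_a - mean(image_a))
  Fb <- stats::fft(image_b - mean(image_b))

  # signed frequency index per axis, in bins
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  kx <- matrix(k, n, n)
  ky <- t(kx)
  ring <- round(sqrt(kx^2 + ky^2))          # integer-radius ring index

  n_rings <- floor(n / 2)
  idx <- which(ring >= 1 & ring <= n_rings)
  rg <- ring[idx]
  cross <- rowsum(Re(Fa[idx] * Conj(Fb[idx])), rg)[, 1]
  pa <- rowsum(Mod(Fa[idx])^2, rg)[, 1]
  pb <- rowsum(Mod(Fb[idx])^2, rg)[, 1]
  n_ring <- rowsum(rep(1, length(rg)), rg)[, 1]

  denom <- sqrt(pa * pb)
  corr <- ifelse(denom > 0, cross / denom, 0)
  freqs <- as.numeric(names(cross)) / n     # cycles per pixel

  thr <- switch(criterion,
    "fixed-1/7" = rep(1 / 7, length(freqs)),
    "half-bit" = (0.2071 + 1.9102 / sqrt(n_ring)) /
                 (1.2071 + 0.9102 / sqrt(n_ring))
  )

  below <- which(corr < thr)
  if (length(below) == 0) {
    f_star <- NA_real_
    res <- NA_real_
    beyond <- TRUE
  } else {
    i <- below[1]
    if (i == 1) {
      f_star <- freqs[1]
    } else {
      # linear interpolation of (corr - thr) between rings i-1 and i
      d0 <- corr[i - 1] - thr[i - 1]
      d1 <- corr[i] - thr[i]
      w <- d0 / (d0 - d1)
      f_star <- freqs[i - 1] + w * (freqs[i] - freqs[i - 1])
    }
    res <- pixel_pitch / f_star
    beyond <- FALSE
  }

  structure(
    list(ring_freqs = freqs, correlation = unname(corr),
         threshold = unname(thr), n_ring = unname(n_ring),
         criterion = criterion, pixel_pitch = pixel_pitch,
         crossing_freq = f_star, resolution_estimate = res,
         beyond_nyquist = beyond),
    class = "frc_curve"
  )
}

#' @export
print.frc_curve <- function(x, ...) {
  if (x$beyond_nyquist) {
    cat("<frc_curve> no threshold crossing: resolution beyond Nyquist\n")
  } else {
    cat(sprintf("<frc_curve> crossing at %.4f cycles/pixel -> resolution %.1f (pitch %g)\n",
                x$crossing_freq, x$resolution_estimate, x$pixel_pitch))
  }
  invisible(x)
}

#' Single-acquisition FRC from a split stack
#'
#' Standard split-data FRC protocol for a single acquisition: odd-indexed
#' and even-indexed frames form two half stacks, each is processed by the
#' dynamic pipeline independently, and the FRC is computed between the two
#' single-channel band-sum images (the sum of the three raw integrated band
#' maps).
#'
#' @param stack A [raw_stack()] with at least 8 frames and square images.
#' @inheritParams dynamic_pipeline
#' @inheritParams frc
#' @return An `frc_curve` (see [frc()]); `pixel_pitch` is taken from the
#'   stack metadata so the resolution estimate is in nm.
#' @export
split_stack_frc <- function(stack, bands = band_definition(),
                            cfg = render_config(),
                            criterion = c("fixed-1/7", "half-bit")) {
  if (!inherits(stack, "raw_stack"))
    stop_structural("stack must be a raw_stack object")
  tN <- dim(stack$frames)[1]
  if (tN < 8)
    stop_degenerate("split-stack FRC needs at least 8 frames")
  half_meta <- function(n) {
    m <- as_meta_list(stack$meta)
    m$n_frames <- n
    meta_from_list(m)
  }
  odd <- seq(1, tN, by = 2)
  even <- seq(2, tN, by = 2)
  sub <- function(ix) raw_stack(stack$frames[ix, , , drop = FALSE],
                                half_meta(length(ix)))
  band_sum <- function(s) {
    im <- dynamic_pipeline(s, bands, cfg)
    im$band_maps$low + im$band_maps$mid + im$band_maps$high
  }
  frc(band_sum(sub(odd)), band_sum(sub(even)),
      criterion = criterion, pixel_pitch = stack$meta$pixel_pitch)
}

#' Contrast-to-noise ratio between two regions of interest
#'
#' \deqn{CNR = |\mu_{sig} - \mu_{bg}| / \sigma_{bg}} with the background
#' standard deviation computed with denominator `N - 1`. Invariant to
#' intensity scaling and offsets.
#'
#' @param image A numeric matrix.
#' @param roi_signal,roi_background Logical masks of the image shape (or
#'   index vectors); must be non-empty and disjoint.
#' @return A single non-negative number.
#' @examples
#' img <- matrix(c(rep(10, 8), 0, 2, 2, 4), 3, 4)
#' cnr(img, col(img) <= 2, col(img) >= 3)
#' @export
cnr <- function(image, roi_signal, roi_background) {
  if (!is.matrix(image))
    stop_structural("image must be a matrix")
  sig_idx <- roi_indices(image, roi_signal, "roi_signal")
  bg_idx <- roi_indices(image, roi_background, "roi_background")
  if (length(intersect(sig_idx, bg_idx)) > 0)
    stop_structural("signal and background ROIs must be disjoint")
  s_bg <- stats::sd(image[bg_idx])
  if (!is.finite(s_bg) || s_bg == 0)
    stop_numerical("background standard deviation is zero: CNR undefined")
  abs(mean(image[sig_idx]) - mean(image[bg_idx])) / s_bg
}

roi_indices <- function(image, roi, what) {
  if (is.logical(roi)) {
    if (!identical(dim(roi), dim(image)))
      stop_structural("%s mask must match the image shape", what)
    idx <- which(roi)
  } else {
    idx <- as.integer(roi)
    if (any(idx < 1) || any(idx > length(image)))
      stop_structural("%s indices out of range", what)
  }
  if (length(idx) < 2)
    stop_structural("%s must contain at least 2 pixels", what)
  idx
}
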