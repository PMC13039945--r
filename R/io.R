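# TIFF + JSON-sidecar I/O.
#
# The tiff package stores sample values on a normalized [0, 1] scale, so
# arbitrary-range float data (photoelectron counts, amplitude images, band
# maps) are written through a common affine encoding v -> (v - offset)/scale
# at 32 bits per sample, with `intensity_offset` and `intensity_scale`
# recorded in the sidecar and undone on read (relative precision 2^-31 of
# the data range). Integer data up to 65535 (quantized stacks, label masks)
# are written as uint16 and round-trip bit-identically.

sidecar_path <- function(path) paste0(path, ".json")

encode_pages <- function(pages) {
  lo <- min(vapply(pages, min, numeric(1)))
  hi <- max(vapply(pages, max, numeric(1)))
  scale <- hi - lo
  if (scale == 0) scale <- 1
  list(pages = lapply(pages, function(p) (p - lo) / scale),
       offset = lo, scale = scale)
}

write_float_pages <- function(pages, path, sidecar_fields = list()) {
  enc <- encode_pages(pages)
  tiff::writeTIFF(enc$pages, path, bits.per.sample = 32L, reduce = FALSE)
  fields <- c(sidecar_fields,
              list(tiff_format = "float32",
                   intensity_offset = enc$offset,
                   intensity_scale = enc$scale))
  jsonlite::write_json(fields, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_pages <- function(path, meta_sidecar = NULL) {
  if (!file.exists(path))
    stop_io("file not found: %s", path)
  fields <- read_sidecar(path, meta_sidecar)
  fmt <- if (is.null(fields$tiff_format)) "float32" else fields$tiff_format
  as_is <- identical(fmt, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # tolerate single-channel planes
    p
  })
  if (!as_is) {
    off <- if (is.null(fields$intensity_offset)) 0 else fields$intensity_offset
    sc <- if (is.null(fields$intensity_scale)) 1 else fields$intensity_scale
    pages <- lapply(pages, function(p) p * sc + off)
  }
  list(pages = pages, fields = fields)
}

read_sidecar <- function(path, meta_sidecar) {
  sc <- if (is.null(meta_sidecar)) sidecar_path(path) else meta_sidecar
  if (!file.exists(sc)) return(list())
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write a raw stack as multi-page TIFF with a JSON metadata sidecar
#'
#' The canonical on-disk format: one TIFF page per frame plus a
#' `<path>.json` sidecar holding the acquisition metadata (frame rate,
#' pixel pitch, source spectrum, camera characteristics) and the storage
#' encoding.
#'
#' @param stack A [raw_stack()].
#' @param path Output TIFF path.
#' @param format `"float32"` (any intensities; stored on a recorded affine
#'   scale with 2^-31 relative precision) or `"uint16"` (integer data up to
#'   65535, e.g. quantized stacks; round-trips bit-identically).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("float32", "uint16")) {
  if (!inherits(stack, "raw_stack"))
    stop_structural("stack must be a raw_stack object")
  format <- match.arg(format)
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[1]), function(i) stack$frames[i, , ])
  meta_fields <- as_meta_list(stack$meta)
  if (format == "uint16") {
    if (max(stack$frames) > 65535 || any(stack$frames != round(stack$frames)))
      stop_parameter("uint16 output requires integer intensities <= 65535; use float32")
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
    jsonlite::write_json(c(meta_fields, list(tiff_format = "uint16")),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
    invisible(path)
  } else {
    write_float_pages(pages, path, meta_fields)
  }
}

#' Read a raw stack from a multi-page TIFF
#'
#' Reads all pages into a T x Y x X stack. Acquisition metadata comes from
#' the JSON sidecar (`<path>.json`) when present; missing fields fall back
#' to the instrument defaults of [acquisition_meta()], and a missing frame
#' rate is defaulted to 500 Hz with a warning.
#'
#' @param path TIFF path.
#' @param meta_sidecar Optional explicit sidecar path; default
#'   `<path>.json` if it exists.
#' @return A [raw_stack()].
#' @export
read_stack <- function(path, meta_sidecar = NULL) {
  rd <- read_pages(path, meta_sidecar)
  pages <- rd$pages
  d0 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d0), logical(1))))
    stop_io("TIFF pages in %s have inconsistent shapes", path)
  if (length(pages) < 2)
    stop_io("a stack needs at least 2 frames; %s has %d page(s)",
            path, length(pages))

  fields <- rd$fields
  if (is.null(fields$frame_rate)) {
    warn_dffocm("no frame rate in metadata for %s; assuming the 500 Hz instrument default",
                path)
    fields$frame_rate <- 500
  }
  fields$n_frames <- length(pages)
  fields$height <- d0[1]
  fields$width <- d0[2]
  meta <- meta_from_list(fields)

  frames <- array(0, c(length(pages), d0[1], d0[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  raw_stack(frames, meta)
}

#' Read four phase-stepped frames from a 4-page TIFF
#'
#' Pages are taken in order as the 0, 90, 180 and 270 degree frames.
#'
#' @inheritParams read_stack
#' @return A [phase_quad()].
#' @export
read_phase_quad <- function(path, meta_sidecar = NULL) {
  rd <- read_pages(path, meta_sidecar)
  pages <- rd$pages
  if (length(pages) != 4)
    stop_io("a phase quad needs exactly 4 TIFF pages; %s has %d",
            path, length(pages))
  fields <- rd$fields
  meta <- if (!is.null(fields$frame_rate)) {
    fields$height <- nrow(pages[[1]])
    fields$width <- ncol(pages[[1]])
    meta_from_list(fields)
  } else NULL
  phase_quad(pages[[1]], pages[[2]], pages[[3]], pages[[4]], meta = meta)
}

#' Write a phase quad as a 4-page TIFF
#'
#' @param quad A [phase_quad()].
#' @inheritParams write_stack
#' @export
write_phase_quad <- function(quad, path) {
  if (!inherits(quad, "phase_quad"))
    stop_structural("quad must be a phase_quad object")
  meta_fields <- if (is.null(quad$meta)) list() else as_meta_list(quad$meta)
  write_float_pages(list(quad$I1, quad$I2, quad$I3, quad$I4), path,
                    meta_fields)
}

#' Write a single float image as TIFF
#'
#' Used for amplitude images, STD maps and band maps; the affine storage
#' encoding goes into the `<path>.json` sidecar.
#'
#' @param values A numeric matrix.
#' @param path Output TIFF path.
#' @export
write_image <- function(values, path) {
  if (!is.matrix(values))
    stop_structural("values must be a matrix")
  write_float_pages(list(values), path)
}

#' Read a single-page float image written by [write_image()]
#' @param path TIFF path.
#' @return A numeric matrix.
#' @export
read_image <- function(path) {
  read_pages(path)$pages[[1]]
}

#' Write an integer label mask as a single-page TIFF
#'
#' @param labels Integer matrix of region labels (0 = background).
#' @param path Output TIFF path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535 || min(labels) < 0)
    stop_parameter("labels must lie in [0, 65535]")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  jsonlite::write_json(list(tiff_format = "uint16"), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_label_mask <- function(path) {
  p <- read_pages(path)$pages[[1]]
  storage.mode(p) <- "integer"
  p
}

#' Write an RGB composite as 8-bit PNG
#'
#' @param rgb A 3 x Y x X array in `[0, 1]` (channels R, G, B), as produced
#'   by [render_rgb()] or found in a `dynamic_image`.
#' @param path Output PNG path.
#' @export
write_rgb_png <- function(rgb, path) {
  d <- dim(rgb)
  if (length(d) != 3 || d[1] != 3)
    stop_structural("rgb must be a 3 x Y x X array")
  img <- aperm(rgb, c(2, 3, 1))
  png::writePNG(img, path)
  invisible(path)
}
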