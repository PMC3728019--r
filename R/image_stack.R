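#' Construct an image stack
#'
#' A minimal container for one channel of a 3-D fluorescence (or
#' bright-field) acquisition: a non-negative pixel array of dimension
#' `(ny, nx, nz)` plus the physical pixel size and z-step.
#'
#' @param pixels Numeric array `(ny, nx, nz)`, or a matrix for a single
#'   slice; values must be finite and non-negative.
#' @param pixel_size_um Lateral pixel size in microns.
#' @param z_step_um Distance between z-slices in microns (default 0.4).
#' @param channel Channel name (e.g. a gene, or `"brightfield"`).
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size_um, z_step_um = 0.4,
                        channel = "unknown") {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stopf("'pixels' must be a (ny, nx, nz) array")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stopf("'pixels' must be finite")
  if (any(pixels < 0)) stopf("'pixels' must be non-negative")
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  check_number(z_step_um, "z_step_um", lower = 0, strict_lower = TRUE)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel = as.character(channel)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack '%s': %d x %d px, %d z-slices (%g um/px, %g um z-step)\n",
              x$channel, d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

n_slices <- function(stack) dim(stack$pixels)[3L]

# 1-based index of the slice at the cell mid-plane
central_slice_index <- function(stack) floor(n_slices(stack) / 2) + 1L

central_slice <- function(stack) stack$pixels[, , central_slice_index(stack)]

#' Write / read an image stack as multi-page TIFF
#'
#' Stacks are stored one z-slice per page as 16-bit TIFF. Pixel values
#' must lie in `[0, 1]` (the synthetic renderer keeps intensities in this
#' range); values are quantized to 16 bits on write.
#'
#' @param stack An [image_stack()].
#' @param path File path.
#' @param pixel_size_um,z_step_um,channel Metadata for `read_stack` (TIFF
#'   pages carry no calibration in this minimal format).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  px <- stack$pixels
  if (max(px) > 1) stopf("pixel values must be <= 1 for 16-bit TIFF output")
  pages <- lapply(seq_len(dim(px)[3L]), function(k) px[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size_um, z_step_um = 0.4,
                       channel = "unknown") {
  if (!file.exists(path)) stopf("image stack not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  px <- array(0, c(dim(pages[[1L]])[1:2], length(pages)))
  for (k in seq_along(pages)) px[, , k] <- pages[[k]]
  image_stack(px, pixel_size_um, z_step_um, channel)
}

#' Write / read a cell label mask as 16-bit TIFF
#'
#' Integer labels (0 = background) are stored scaled by 1/65535 so that
#' the round trip through a 16-bit grayscale TIFF is exact for up to
#' 65535 cells.
#'
#' @param labels Integer matrix of labels.
#' @param path File path.
#' @return `write_label_mask` returns `path` invisibly; `read_label_mask`
#'   returns the integer label matrix.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L) stopf("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stopf("label mask not found: %s", path)
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
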