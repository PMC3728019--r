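#' Segment cells from a bright-field image
#'
#' Marker-guided watershed segmentation of a monolayer of cells:
#' 1. edge detection (Sobel gradient magnitude with hysteresis
#'    thresholding) on the central bright-field slice;
#' 2. morphological closing of the detected boundaries;
#' 3. one marker per region enclosed by the boundaries (its centroid is
#'    reported by [mask_table()]);
#' 4. marker-guided watershed ([EBImage::propagate()]) on the distance
#'    transform of the boundary image, restricted to the area the
#'    boundaries enclose;
#' 5. an area filter that drops implausibly small or large segments
#'    (automated replacement for manual curation of mis-segmentations).
#'
#' A blank or constant image yields zero labels without error.
#'
#' @param brightfield An [image_stack()]; the central slice is used.
#' @param min_area_px,max_area_px Area bounds (pixels) for accepted cells.
#' @param edge_frac_hi,edge_frac_lo Hysteresis thresholds as fractions of
#'   the maximum gradient magnitude.
#' @param close_radius Radius (pixels) of the disk used to close gaps in
#'   the detected boundaries.
#' @param marker_min_area Minimum area (pixels) of an enclosed region for
#'   it to seed a marker.
#' @return A list of class `label_mask`: `labels` (integer matrix, 0 =
#'   background, k > 0 = cell k with contiguous labels) and
#'   `pixel_size_um`.
#' @export
segment_cells <- function(brightfield,
                          min_area_px = 300,
                          max_area_px = Inf,
                          edge_frac_hi = 0.4,
                          edge_frac_lo = 0.2,
                          close_radius = 3,
                          marker_min_area = 25) {
  stopifnot(inherits(brightfield, "image_stack"))
  img <- central_slice(brightfield)
  empty <- structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          pixel_size_um = brightfield$pixel_size_um),
                     class = "label_mask")

  # Sobel gradient magnitude
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 8
  gx <- EBImage::filter2(img, kx)
  gy <- EBImage::filter2(img, t(kx))
  grad <- sqrt(gx^2 + gy^2)
  gmax <- max(grad)
  if (gmax <= 0) return(empty)

  # hysteresis: keep weak-edge components that contain a strong pixel
  strong <- grad > edge_frac_hi * gmax
  weak <- grad > edge_frac_lo * gmax
  if (!any(strong)) return(empty)
  wl <- EBImage::bwlabel(weak)
  keep <- sort(unique(wl[strong]))
  keep <- keep[keep > 0]
  edges <- matrix(wl %in% keep, nrow(img), ncol(img))

  brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
  closed <- EBImage::closing(edges, brush) > 0
  filled <- EBImage::fillHull(closed) > 0

  # markers: the regions enclosed by the boundaries (tiny enclosures are
  # noise, not cells); seeding the watershed with the whole enclosed
  # region rather than a single centroid pixel keeps the flooding from
  # leaking across shallow ridges between touching cells
  inner <- filled & !closed
  il <- EBImage::bwlabel(inner)
  nlab <- max(il)
  if (nlab == 0) return(empty)
  area <- tabulate(il[il > 0], nbins = nlab)
  ok <- which(area >= marker_min_area)
  if (length(ok) == 0) return(empty)
  remap0 <- integer(nlab)
  remap0[ok] <- seq_along(ok)
  seeds <- matrix(0L, nrow(img), ncol(img))
  pos <- il > 0
  seeds[pos] <- remap0[il[pos]]

  # watershed on the distance transform of the boundary image
  dist <- EBImage::distmap(!closed)
  ws <- EBImage::propagate(max(dist) - dist, seeds, mask = filled)
  labels <- matrix(as.integer(ws), nrow(img), ncol(img))

  # area filter replaces manual curation of mis-segmentations
  n <- max(labels)
  if (n > 0) {
    a <- tabulate(labels[labels > 0], nbins = n)
    ok <- which(a >= min_area_px & a <= max_area_px)
    remap <- integer(n)
    remap[ok] <- seq_along(ok)
    labels[labels > 0] <- remap[labels[labels > 0]]
  }
  structure(list(labels = labels,
                 pixel_size_um = brightfield$pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d cells in a %d x %d px field\n",
              max(x$labels), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Per-cell geometry of a label mask
#'
#' @param mask A `label_mask` from [segment_cells()], or an integer label
#'   matrix (then `pixel_size_um` must be given).
#' @param pixel_size_um Pixel size, used to convert centroids to microns.
#' @return Data frame `cell_id, area_px, x_px, y_px, x_um, y_um`.
#' @export
mask_table <- function(mask, pixel_size_um = NULL) {
  if (inherits(mask, "label_mask")) {
    labels <- mask$labels
    pixel_size_um <- pixel_size_um %||% mask$pixel_size_um
  } else {
    labels <- mask
    if (is.null(pixel_size_um)) stopf("'pixel_size_um' is required")
  }
  n <- max(labels)
  if (n == 0)
    return(data.frame(cell_id = integer(0), area_px = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0)))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  area <- tabulate(lab, nbins = n)
  x_px <- vapply(split(idx[, 2], lab), mean, numeric(1))
  y_px <- vapply(split(idx[, 1], lab), mean, numeric(1))
  data.frame(cell_id = seq_len(n), area_px = area,
             x_px = unname(x_px), y_px = unname(y_px),
             x_um = unname(x_px) * pixel_size_um,
             y_um = unname(y_px) * pixel_size_um)
}
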