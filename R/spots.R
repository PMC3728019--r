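# Laplacian-of-Gaussian spot enhancement and 3-D connected-component
# spot calling.

log_kernel <- function(sigma) {
  # negated, scale-normalized LoG: positive response at bright blobs
  half <- ceiling(4 * sigma)
  ax <- (-half):half
  g <- exp(-ax^2 / (2 * sigma^2))
  G <- outer(g, g)
  G <- G / sum(G)
  r2 <- outer(ax^2, ax^2, `+`)
  k <- -(r2 - 2 * sigma^2) / sigma^4 * G
  k * sigma^2  # scale normalization
}

# per-slice LoG response of a stack
log_response <- function(stack, sigma_px) {
  k <- log_kernel(sigma_px)
  px <- stack$pixels
  out <- array(0, dim(px))
  for (z in seq_len(dim(px)[3L]))
    out[, , z] <- EBImage::filter2(px[, , z], k)
  out
}

# 3-D connected components (26-connectivity) of a logical array:
# 8-connected labeling per slice, then union-find merging of labels in
# adjacent slices that touch within a 3 x 3 xy-neighborhood.
label_components_3d <- function(mask) {
  dims <- dim(mask)
  nz <- dims[3L]
  lab <- array(0L, dims)
  offset <- 0L
  nper <- integer(nz)
  for (z in seq_len(nz)) {
    l2 <- EBImage::bwlabel(mask[, , z])
    nper[z] <- max(l2)
    l2[l2 > 0] <- l2[l2 > 0] + offset
    lab[, , z] <- l2
    offset <- offset + nper[z]
  }
  ntot <- offset
  if (ntot == 0L) return(lab)

  parent <- seq_len(ntot)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  ny <- dims[1L]; nx <- dims[2L]
  for (z in seq_len(nz - 1L)) {
    a <- lab[, , z]; b <- lab[, , z + 1L]
    if (nper[z] == 0L || nper[z + 1L] == 0L) next
    for (dy in -1:1) for (dx in -1:1) {
      ya <- max(1, 1 + dy):min(ny, ny + dy)
      xa <- max(1, 1 + dx):min(nx, nx + dx)
      yb <- max(1, 1 - dy):min(ny, ny - dy)
      xb <- max(1, 1 - dx):min(nx, nx - dx)
      pa <- a[ya, xa]; pb <- b[yb, xb]
      hit <- pa > 0L & pb > 0L
      if (any(hit)) {
        prs <- unique(cbind(pa[hit], pb[hit]))
        for (r in seq_len(nrow(prs))) union(prs[r, 1L], prs[r, 2L])
      }
    }
  }
  root <- vapply(seq_len(ntot), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Detect diffraction-limited spots in a FISH image stack
#'
#' Runs a scale-normalized Laplacian-of-Gaussian filter over each optical
#' slice to enhance diffraction-limited signals, thresholds the response,
#' groups supra-threshold voxels into 3-D connected regions
#' (26-connectivity, so a spot spanning several slices is counted once),
#' and reports one spot per region at its regional response maximum.
#'
#' @param fish An [image_stack()].
#' @param sigma_px LoG scale in pixels (should match the spot width).
#' @param threshold Positive threshold on the LoG response.
#' @return Data frame of class `spot_table` with one row per spot:
#'   `y, x, z` (pixel coordinates of the regional maximum, 1-based),
#'   `peak` (LoG response at the maximum) and `n_voxels` (region size).
#' @export
detect_spots <- function(fish, sigma_px = 1.5, threshold) {
  stopifnot(inherits(fish, "image_stack"))
  check_number(sigma_px, "sigma_px", 0, strict_lower = TRUE)
  check_number(threshold, "threshold")
  if (threshold <= 0) stopf("'threshold' must be > 0")
  resp <- log_response(fish, sigma_px)
  spots_from_response(resp, threshold)
}

spots_from_response <- function(resp, threshold) {
  lab <- label_components_3d(resp > threshold)
  n <- max(lab)
  out <- data.frame(y = integer(0), x = integer(0), z = integer(0),
                    peak = numeric(0), n_voxels = integer(0))
  if (n > 0) {
    idx <- which(lab > 0L)
    by_lab <- split(idx, lab[idx])
    dims <- dim(resp)
    rows <- lapply(by_lab, function(ii) {
      vals <- resp[ii]
      best <- ii[which.max(vals)]
      ai <- arrayInd(best, dims)
      data.frame(y = ai[1L], x = ai[2L], z = ai[3L],
                 peak = max(vals), n_voxels = length(ii))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  }
  class(out) <- c("spot_table", "data.frame")
  out
}

count_components <- function(resp, threshold) max(label_components_3d(resp > threshold))

#' Automatic spot-detection threshold by the plateau criterion
#'
#' Sweeps a log-spaced grid of thresholds over the LoG response and counts
#' the detected spots at each. Across the sweep the count falls steeply
#' while noise is being thresholded out, stays constant over a wide
#' plateau where every true spot and nothing else is detected, and decays
#' again as real spots are lost. The returned threshold is the (geometric)
#' midpoint of the widest plateau, making the selection reproducible and
#' free of manual tuning; it is also equivariant to global intensity
#' scaling because the sweep bounds derive from the response maximum.
#'
#' @param fish An [image_stack()].
#' @param sigma_px LoG scale in pixels.
#' @param n_sweep Number of thresholds in the sweep.
#' @param span Ratio between the largest and smallest swept threshold.
#' @param min_run Minimum plateau length (sweep points) to accept; with no
#'   such plateau (e.g. a monotone count curve) the sweep midpoint is
#'   returned with a warning.
#' @return The selected threshold, with attributes `sweep` (data frame of
#'   `threshold, n_spots`) and `plateau_count`.
#' @export
select_threshold <- function(fish, sigma_px = 1.5, n_sweep = 40L,
                             span = 100, min_run = 3L) {
  stopifnot(inherits(fish, "image_stack"))
  resp <- log_response(fish, sigma_px)
  hi <- max(resp)
  if (hi <= 0) {
    warnf("image has no positive LoG response; returning a nominal threshold")
    return(structure(.Machine$double.eps,
                     sweep = data.frame(threshold = numeric(0),
                                        n_spots = integer(0)),
                     plateau_count = 0L))
  }
  thr <- exp(seq(log(hi / span), log(hi * 0.999), length.out = n_sweep))
  counts <- vapply(thr, function(t) count_components(resp, t), integer(1))
  sweep <- data.frame(threshold = thr, n_spots = counts)

  # runs of constant positive count
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values > 0 & r$lengths >= min_run)
  if (length(cand) == 0L) {
    warnf("no plateau in the spot-count curve; returning the sweep midpoint")
    return(structure(sqrt(thr[1L] * thr[n_sweep]), sweep = sweep,
                     plateau_count = 0L))
  }
  best <- cand[which.max(r$lengths[cand] + seq_along(r$lengths)[cand] * 1e-9)]
  i0 <- starts[best]; i1 <- ends[best]
  structure(sqrt(thr[i0] * thr[i1]), sweep = sweep,
            plateau_count = r$values[best])
}
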