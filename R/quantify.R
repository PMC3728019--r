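#' Assign detected spots to segmented cells
#'
#' Each spot is assigned to the cell label under its (y, x) position;
#' spots falling on background (label 0) are discarded and reported.
#'
#' @param spots A `spot_table` from [detect_spots()] (needs `y`, `x`).
#' @param mask A `label_mask` from [segment_cells()] or an integer label
#'   matrix.
#' @return A list: `counts` (data frame `cell_id, count` covering every
#'   cell in the mask) and `n_background` (number of discarded spots).
#' @export
assign_spots <- function(spots, mask) {
  labels <- if (inherits(mask, "label_mask")) mask$labels else mask
  n <- max(labels)
  if (nrow(spots) == 0) {
    return(list(counts = data.frame(cell_id = seq_len(n),
                                    count = rep(0L, n)),
                n_background = 0L))
  }
  iy <- pmin(pmax(as.integer(round(spots$y)), 1L), nrow(labels))
  ix <- pmin(pmax(as.integer(round(spots$x)), 1L), ncol(labels))
  lab <- labels[cbind(iy, ix)]
  list(counts = data.frame(cell_id = seq_len(n),
                           count = tabulate(lab[lab > 0], nbins = n)),
       n_background = sum(lab == 0L))
}

#' Background-subtracted total fluorescence per cell
#'
#' On the optical slice at the cell mid-plane, computes the mean
#' fluorescence of every segmented cell, takes the minimum of these means
#' as the image background, and reports for each cell the sum of
#' (pixel - background) over its area, clamped at zero. The result is
#' invariant to adding a constant to the whole image.
#'
#' @param channel An [image_stack()].
#' @param mask A `label_mask` or integer label matrix.
#' @return Data frame `cell_id, total_fluor, mean_fluor, area_px`; empty
#'   when the mask has no cells.
#' @export
quantify_fluorescence <- function(channel, mask) {
  stopifnot(inherits(channel, "image_stack"))
  labels <- if (inherits(mask, "label_mask")) mask$labels else mask
  n <- max(labels)
  if (n == 0)
    return(data.frame(cell_id = integer(0), total_fluor = numeric(0),
                      mean_fluor = numeric(0), area_px = integer(0)))
  img <- central_slice(channel)
  if (!all(dim(img) == dim(labels)))
    stopf("channel and mask dimensions differ")
  inside <- labels > 0
  lab <- labels[inside]
  vals <- img[inside]
  sums <- vapply(split(vals, lab), sum, numeric(1))
  area <- tabulate(lab, nbins = n)
  means <- unname(sums) / area
  background <- min(means)
  total <- pmax(unname(sums) - area * background, 0)
  data.frame(cell_id = seq_len(n), total_fluor = total,
             mean_fluor = means, area_px = area)
}

#' Extrapolate unresolvable high-expresser counts from total fluorescence
#'
#' In cells with very many transcripts, individual spots overlap and
#' cannot be resolved, but total FISH fluorescence remains linear in the
#' transcript number. A least-squares line through the origin is fitted
#' to (count, total fluorescence) over calibration cells with
#' `0 < count < resolvable_max`; unresolvable cells then get their count
#' replaced by `total_fluor / slope`. All other cells are unchanged.
#'
#' A cell is deemed unresolvable when its computed count is at/above
#' `resolvable_max`, or (with `fluor_trigger = TRUE`, the default) when
#' its fluorescence exceeds what `resolvable_max` resolvable transcripts
#' would produce: in a crowded cell the connected-region spot counter
#' collapses many overlapping transcripts into few regions, so the
#' computed count of exactly such cells is small while the fluorescence
#' stays proportional to the true content. For the same reason the
#' calibration is two-stage: a robust per-cell ratio (median of
#' fluorescence/count) first screens out cells whose fluorescence is far
#' beyond the resolvable range, and the least-squares slope is fitted on
#' the remainder.
#'
#' @param cells Data frame with the count and fluorescence columns.
#' @param count_col,fluor_col Column names.
#' @param resolvable_max Counts at/above this are considered unresolvable
#'   (default 200).
#' @param fluor_trigger Also extrapolate cells whose fluorescence exceeds
#'   `slope * resolvable_max` (default `TRUE`).
#' @return `cells` with updated counts; attributes `slope` and
#'   `n_calibration`.
#' @export
extrapolate_counts <- function(cells, count_col, fluor_col,
                               resolvable_max = 200,
                               fluor_trigger = TRUE) {
  stopifnot(is.data.frame(cells),
            count_col %in% names(cells), fluor_col %in% names(cells))
  check_number(resolvable_max, "resolvable_max", 0, strict_lower = TRUE)
  cnt <- cells[[count_col]]
  flr <- cells[[fluor_col]]
  pre <- cnt > 0 & cnt < resolvable_max
  if (sum(pre) < 5)
    stopf("need >= 5 calibration cells with 0 < count < %g, got %d",
          resolvable_max, sum(pre))
  s0 <- median(flr[pre] / cnt[pre])
  calib <- which(pre & (!fluor_trigger | flr < s0 * resolvable_max))
  if (length(calib) < 5)
    stopf("need >= 5 calibration cells with 0 < count < %g, got %d",
          resolvable_max, length(calib))
  slope <- sum(flr[calib] * cnt[calib]) / sum(cnt[calib]^2)
  if (slope <= 0) stopf("non-positive calibration slope")
  high <- cnt >= resolvable_max
  if (fluor_trigger) high <- high | flr >= slope * resolvable_max
  if (any(high)) cells[[count_col]][high] <- flr[high] / slope
  structure(cells, slope = slope, n_calibration = length(calib))
}
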