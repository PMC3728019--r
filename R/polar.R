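#' Polar-coordinate representation of joint transcription-factor counts
#'
#' Converts per-cell (Tbx21, Gata3) transcript counts `(t, g)` into polar
#' coordinates: the distance from the origin `sqrt(t^2 + g^2)` and the
#' angle with the Tbx21 axis `atan(g / t)`, in `[0, pi/2]`.
#' A cell with `theta` near 0 is Th1-like (mostly Tbx21), near `pi/2`
#' Th2-like (mostly Gata3), and intermediate angles are mixed states.
#' At the origin (both counts zero) the angle is undefined and set to 0
#' by convention; such
#' cells fall below any sensible [filter_r()] radius anyway.
#'
#' @param t,g Non-negative count vectors (recycled to common length).
#' @return Data frame `t, g, r, theta`.
#' @examples
#' to_polar(c(10, 30, 0, 6), c(10, 0, 20, 8))
#' @export
to_polar <- function(t, g) {
  if (length(t) != length(g)) {
    n <- max(length(t), length(g))
    t <- rep_len(t, n); g <- rep_len(g, n)
  }
  if (anyNA(t) || anyNA(g)) stopf("counts must not contain NA")
  if (any(t < 0) || any(g < 0)) stopf("counts must be non-negative")
  r <- sqrt(t^2 + g^2)
  theta <- atan2(g, t)  # 0 when t = g = 0
  data.frame(t = t, g = g, r = r, theta = theta)
}

#' Exclude low-count cells from the polar analysis
#'
#' The angle of a cell with few transcripts is dominated by count noise:
#' cells whose radius is below `r_min` (default 10) are excluded before
#' any distributional analysis of `theta`. The rule is strict: a radius
#' exactly equal to `r_min` is kept.
#'
#' @param cells Data frame with an `r` column (from [to_polar()]).
#' @param r_min Exclusion radius (default 10).
#' @return List with `kept` (the retained rows) and `n_excluded`.
#' @export
filter_r <- function(cells, r_min = 10) {
  stopifnot(is.data.frame(cells), "r" %in% names(cells))
  check_number(r_min, "r_min", 0)
  keep <- cells$r >= r_min
  list(kept = cells[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Summarize a theta distribution
#'
#' Histogram (density-normalized, equal-width bins on `[0, pi/2]`),
#' median, and a U-shape index: the fraction of cells with `theta` below
#' `u_lo` or above `u_hi`. Under a uniform angle distribution the index
#' is `(u_lo + pi/2 - u_hi) / (pi/2)` (0.5 at the defaults); values near
#' 1 indicate mutually exclusive expression, with most cells on an axis.
#'
#' @param theta Angles in `[0, pi/2]`; must be non-empty.
#' @param n_bins Number of histogram bins (default 10).
#' @param u_lo,u_hi U-shape index thresholds (defaults `pi/8`, `3*pi/8`).
#' @param n_excluded Number of cells excluded upstream (bookkeeping).
#' @return List of class `theta_summary`: `n_kept`, `n_excluded`,
#'   `median_theta`, `hist` (list `breaks`, `density`), `u_index`.
#' @export
theta_summary <- function(theta, n_bins = 10, u_lo = pi / 8,
                          u_hi = 3 * pi / 8, n_excluded = 0) {
  if (length(theta) == 0) stopf("'theta' is empty")
  if (anyNA(theta) || any(theta < 0 | theta > pi / 2))
    stopf("'theta' must lie in [0, pi/2]")
  check_count(n_bins, "n_bins", lower = 1L)
  breaks <- seq(0, pi / 2, length.out = n_bins + 1L)
  h <- graphics::hist(theta, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  structure(
    list(n_kept = length(theta), n_excluded = n_excluded,
         median_theta = median(theta),
         hist = list(breaks = breaks, density = h$density),
         u_index = mean(theta < u_lo | theta > u_hi)),
    class = "theta_summary")
}

#' @export
print.theta_summary <- function(x, ...) {
  cat(sprintf("theta summary: %d cells kept, %d excluded\n",
              x$n_kept, x$n_excluded))
  cat(sprintf("  median theta %.4f (pi/4 = %.4f), u_index %.3f\n",
              x$median_theta, pi / 4, x$u_index))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs; the
#' p-value uses the asymptotic Kolmogorov law. Used to compare theta
#' distributions between culture conditions.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' One-sample uniformity test for theta
#'
#' Kolmogorov-Smirnov test of the angles against the Uniform(0, pi/2)
#' CDF. A uniform angle distribution is the hallmark of cells exploring
#' every intermediate Th1/Th2 state without bias.
#'
#' @param theta Angles in `[0, pi/2]`; must be non-empty.
#' @return List with `D` and `p`.
#' @export
uniformity_test <- function(theta) {
  if (length(theta) == 0) stopf("'theta' is empty")
  if (any(theta < 0 | theta > pi / 2))
    stopf("'theta' must lie in [0, pi/2]")
  kt <- suppressWarnings(ks.test(theta, punif, 0, pi / 2))
  list(D = unname(kt$statistic), p = kt$p.value)
}
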