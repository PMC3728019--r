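#' Fraction of ON cells
#'
#' Fraction of cells with a count strictly above the threshold (an ON
#' cell is "more than `threshold` transcripts"; a count equal to the
#' threshold is OFF).
#'
#' @param counts Non-empty numeric vector.
#' @param threshold ON threshold (default 20, the Ifng convention; use 50
#'   for Il4).
#' @return Fraction in `[0, 1]`.
#' @export
on_fraction <- function(counts, threshold = 20) {
  if (length(counts) == 0) stopf("'counts' is empty")
  check_number(threshold, "threshold", lower = 0)
  mean(counts > threshold)
}

#' Percent reduction between two means
#'
#' `100 * (1 - mean_test / mean_ref)`, rounded to the nearest integer for
#' reporting (e.g. knockout versus wild-type expression). The unrounded
#' value is kept as attribute `raw`.
#'
#' @param mean_ref Reference mean (must be > 0).
#' @param mean_test Test mean.
#' @return Rounded percent reduction.
#' @export
percent_reduction <- function(mean_ref, mean_test) {
  check_number(mean_ref, "mean_ref")
  check_number(mean_test, "mean_test")
  if (mean_ref <= 0) stopf("'mean_ref' must be > 0")
  raw <- 100 * (1 - mean_test / mean_ref)
  structure(round(raw), raw = raw)
}

#' Pearson correlation with a t-test p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `R` (sample correlation) and `p` (two-sided).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("'x' and 'y' differ in length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input")
  ct <- cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value)
}

#' Distance from every cell to its nearest cytokine producer
#'
#' A producer is a cell with strictly more than `threshold` transcripts.
#' Distances are Euclidean between cell centroids (microns); producers
#' themselves are at distance 0.
#'
#' @param x_um,y_um Centroid coordinates in microns.
#' @param counts Cytokine counts, same length.
#' @param threshold Producer threshold (default 20).
#' @return Numeric vector of distances (one per cell).
#' @export
nearest_producer_distance <- function(x_um, y_um, counts, threshold = 20) {
  n <- length(counts)
  stopifnot(length(x_um) == n, length(y_um) == n)
  prod <- which(counts > threshold)
  if (length(prod) == 0) stopf("no producer cells above threshold %g", threshold)
  d2min <- rep(Inf, n)
  for (p in prod) {
    d2 <- (x_um - x_um[p])^2 + (y_um - y_um[p])^2
    d2min <- pmin(d2min, d2)
  }
  sqrt(d2min)
}

#' Is transcription-factor expression independent of producer distance?
#'
#' Pearson correlation between per-cell transcription-factor counts and
#' the distance to the nearest cytokine producer. A well-mixed cytokine
#' milieu (diffusion not rate-limiting) predicts no correlation, which is
#' operationalized as `|R| < cutoff`.
#'
#' @param tf_counts Transcription-factor counts.
#' @param distances Distances from [nearest_producer_distance()].
#' @param cutoff Absolute correlation below which the expression is
#'   reported as uncorrelated with distance (default 0.1).
#' @return List with `R`, `p` and logical `uncorrelated`.
#' @export
distance_correlation_check <- function(tf_counts, distances, cutoff = 0.1) {
  res <- pearson_cor(tf_counts, distances)
  res$uncorrelated <- abs(res$R) < cutoff
  res
}

#' Invariance of TF distributions across cytokine strata
#'
#' Bins cells by their cytokine count into strata (default: zero class,
#' then `[1, 20)`, `[20, 100)`, `[100, 1000)`, `[1000, Inf)`), and
#' compares the transcription-factor count distribution between every
#' pair of sufficiently populated strata with a two-sample
#' Kolmogorov-Smirnov test, Bonferroni-adjusted. If TF expression is
#' decoupled from cytokine expression, no pair differs.
#'
#' @param tf_counts Transcription-factor counts.
#' @param cytokine_counts Cytokine counts, same length.
#' @param strata_edges Increasing break points; a zero class `[0, e1)` is
#'   always prepended.
#' @param min_stratum Strata with fewer cells are dropped with a warning.
#' @return List: `strata_n` (named cell counts per stratum), `pairs`
#'   (data frame `stratum_a, stratum_b, D, p, p_adj`), `max_D`,
#'   `min_p_adj`, `n_dropped_strata`.
#' @export
conditional_invariance <- function(tf_counts, cytokine_counts,
                                   strata_edges = c(1, 20, 100, 1000, Inf),
                                   min_stratum = 20) {
  n <- length(tf_counts)
  stopifnot(length(cytokine_counts) == n)
  if (is.unsorted(strata_edges, strictly = TRUE))
    stopf("'strata_edges' must be strictly increasing")
  breaks <- unique(c(0, strata_edges, Inf))
  strat <- cut(cytokine_counts, breaks = breaks, right = FALSE,
               include.lowest = TRUE)
  tab <- table(strat)
  keep <- names(tab)[tab >= min_stratum]
  dropped <- sum(tab > 0 & tab < min_stratum)
  if (dropped > 0)
    warnf("%d stratum(-a) with fewer than %d cells dropped", dropped,
          min_stratum)
  if (length(keep) < 2)
    stopf("need at least 2 strata with >= %d cells", min_stratum)
  groups <- lapply(keep, function(k) tf_counts[strat == k])
  prs <- utils::combn(length(keep), 2)
  pairs <- data.frame(stratum_a = keep[prs[1, ]], stratum_b = keep[prs[2, ]],
                      D = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(prs))) {
    kt <- ks_two_sample(groups[[prs[1, i]]], groups[[prs[2, i]]])
    pairs$D[i] <- kt$D
    pairs$p[i] <- kt$p
  }
  pairs$p_adj <- pmin(pairs$p * nrow(pairs), 1)
  list(strata_n = as.integer(tab[keep]) |> stats::setNames(keep),
       pairs = pairs,
       max_D = max(pairs$D),
       min_p_adj = min(pairs$p_adj),
       n_dropped_strata = dropped)
}

#' Correlation between ON-cell fraction and mean TF level over time
#'
#' Pearson correlation across time points of the fraction of
#' cytokine-transcribing cells against the mean transcription-factor
#' count, testing whether cytokine activity tracks factor levels at the
#' population level.
#'
#' @param fractions_by_time ON fractions, one per time point (>= 3).
#' @param mean_tf_by_time Mean TF counts, same length.
#' @return List with `R` and `p`.
#' @export
timecourse_fraction_tf_correlation <- function(fractions_by_time,
                                               mean_tf_by_time) {
  if (length(fractions_by_time) < 3) stopf("need at least 3 time points")
  pearson_cor(fractions_by_time, mean_tf_by_time)
}
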