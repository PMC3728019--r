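#' Parameters for the synthetic count-table generator
#'
#' Bundles the statistical regime under which joint transcription-factor
#' (Tbx21, Gata3) and cytokine (Ifng, Il4) transcript counts are drawn.
#' Transcription-factor counts are generated in polar form: a radius `r`
#' drawn from an exponential distribution with mean `r_scale`, and an angle
#' `theta` that is either uniform on `[0, pi/2]` (`"mixed"` regime: cells
#' occupy every intermediate Th1/Th2 state) or concentrated near the two
#' axes (`"exclusive"` regime: cells express mostly one factor). Cytokines
#' are OFF in most cells; a rare fraction (`p_on_*`) is ON with a count
#' drawn from a Gamma distribution, reflecting large transcriptional
#' bursts.
#'
#' The exclusive-regime angle law is an equal mixture of
#' `(pi/2) * Beta(1, theta_conc)` and `pi/2 - (pi/2) * Beta(1, theta_conc)`,
#' which places two symmetric modes at 0 and `pi/2` whose sharpness grows
#' with `theta_conc`.
#'
#' Defaults reflect activated CD4 T cells at 24 h: mean transcription-factor
#' counts of ~34 per cell imply a mean radius of ~53 (under a uniform
#' angle the mean count per axis is `r_scale * 2 / pi`), ON-cell
#' fractions of a few percent, and mean ON-cell burst scales of 159 (Ifng)
#' and 176 (Il4) transcripts.
#'
#' @param regime `"mixed"` or `"exclusive"`.
#' @param r_scale Mean of the exponential radius (transcript units).
#' @param theta_conc Concentration of the exclusive-regime angle near the
#'   axes; larger is more exclusive. Ignored in the mixed regime.
#' @param p_on_ifng,p_on_il4 Probability that a cell is ON for each
#'   cytokine.
#' @param burst_shape_ifng,burst_scale_ifng,burst_shape_il4,burst_scale_il4
#'   Gamma shape and scale of ON-cell cytokine counts.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `regime_params`.
#' @seealso [make_count_table()]
#' @export
regime_params <- function(regime = c("mixed", "exclusive"),
                          r_scale = 53,
                          theta_conc = 8,
                          p_on_ifng = 0.04,
                          p_on_il4 = 0.02,
                          burst_shape_ifng = 1,
                          burst_scale_ifng = 159,
                          burst_shape_il4 = 1,
                          burst_scale_il4 = 176,
                          seed = NULL) {
  regime <- match.arg(regime)
  check_number(r_scale, "r_scale", lower = 0, strict_lower = TRUE)
  check_number(theta_conc, "theta_conc", lower = 0)
  check_number(p_on_ifng, "p_on_ifng", lower = 0, upper = 1)
  check_number(p_on_il4, "p_on_il4", lower = 0, upper = 1)
  for (nm in c("burst_shape_ifng", "burst_scale_ifng",
               "burst_shape_il4", "burst_scale_il4")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  if (!is.null(seed)) check_count(seed, "seed")
  structure(
    list(regime = regime, r_scale = r_scale, theta_conc = theta_conc,
         p_on_ifng = p_on_ifng, p_on_il4 = p_on_il4,
         burst_shape_ifng = burst_shape_ifng,
         burst_scale_ifng = burst_scale_ifng,
         burst_shape_il4 = burst_shape_il4,
         burst_scale_il4 = burst_scale_il4,
         seed = seed),
    class = "regime_params")
}

#' @export
print.regime_params <- function(x, ...) {
  cat("Synthetic count regime:", x$regime, "\n")
  cat(sprintf("  r_scale %g, theta_conc %g\n", x$r_scale, x$theta_conc))
  cat(sprintf("  p_on: Ifng %g, Il4 %g\n", x$p_on_ifng, x$p_on_il4))
  cat(sprintf("  ON-cell Gamma: Ifng (%g, %g), Il4 (%g, %g)\n",
              x$burst_shape_ifng, x$burst_scale_ifng,
              x$burst_shape_il4, x$burst_scale_il4))
  invisible(x)
}

#' Generate a synthetic per-cell transcript count table
#'
#' Draws joint (Tbx21, Gata3) counts by rounding a polar-form continuous
#' draw (see [regime_params()]) and rare bursty cytokine counts for Ifng
#' and Il4. Counts are integers and non-negative by construction.
#'
#' @param params A [regime_params()] object.
#' @param n_cells Number of cells (non-negative integer).
#' @return A list of class `synth_counts` with elements
#'   * `counts`: data frame `cell_id, tbx21, gata3, ifng, il4`;
#'   * `on_state`: data frame `cell_id, on_ifng, on_il4` (logical ground
#'     truth of the cytokine ON draw);
#'   * `latent`: data frame `r, theta` of the continuous draws underlying
#'     the rounded transcription-factor counts;
#'   * `params`: the generator parameters.
#' @examples
#' tab <- make_count_table(regime_params(seed = 1), 100)
#' head(tab$counts)
#' @export
make_count_table <- function(params, n_cells) {
  stopifnot(inherits(params, "regime_params"))
  n_cells <- check_count(n_cells, "n_cells")

  draw <- function() {
    r <- rexp(n_cells, rate = 1 / params$r_scale)
    theta <- if (params$regime == "mixed") {
      runif(n_cells, 0, pi / 2)
    } else {
      b <- rbeta(n_cells, 1, params$theta_conc)
      flip <- runif(n_cells) < 0.5
      ifelse(flip, b, 1 - b) * (pi / 2)
    }
    tbx21 <- round(r * cos(theta))
    gata3 <- round(r * sin(theta))
    on_ifng <- runif(n_cells) < params$p_on_ifng
    ifng <- ifelse(on_ifng,
                   round(rgamma(n_cells, shape = params$burst_shape_ifng,
                                scale = params$burst_scale_ifng)), 0)
    on_il4 <- runif(n_cells) < params$p_on_il4
    il4 <- ifelse(on_il4,
                  round(rgamma(n_cells, shape = params$burst_shape_il4,
                               scale = params$burst_scale_il4)), 0)
    list(r = r, theta = theta, tbx21 = tbx21, gata3 = gata3,
         ifng = ifng, il4 = il4, on_ifng = on_ifng, on_il4 = on_il4)
  }
  d <- with_seed_or_not(params$seed, draw())

  cell_id <- seq_len(n_cells)
  structure(
    list(counts = data.frame(cell_id = cell_id,
                             tbx21 = as.numeric(d$tbx21),
                             gata3 = as.numeric(d$gata3),
                             ifng = as.numeric(d$ifng),
                             il4 = as.numeric(d$il4)),
         on_state = data.frame(cell_id = cell_id,
                               on_ifng = d$on_ifng, on_il4 = d$on_il4),
         latent = data.frame(r = d$r, theta = d$theta),
         params = params),
    class = "synth_counts")
}

#' @export
print.synth_counts <- function(x, ...) {
  cat(sprintf("Synthetic count table: %d cells (%s regime)\n",
              nrow(x$counts), x$params$regime))
  cat(sprintf("  ON cells: Ifng %d, Il4 %d\n",
              sum(x$on_state$on_ifng), sum(x$on_state$on_il4)))
  invisible(x)
}

#' Write / read a per-cell count table as CSV
#'
#' The on-disk format has one row per cell with columns
#' `cell_id, tbx21, gata3, ifng, il4`, optionally `x_um, y_um` (centroid
#' position in microns) and `on_ifng, on_il4` (ground-truth ON states for
#' synthetic tables).
#'
#' @param counts Data frame with at least `cell_id` and one count column.
#' @param path File path.
#' @param layout Optional data frame with `x_um`, `y_um` (row order
#'   matching `counts`).
#' @param on_state Optional data frame with `on_ifng`, `on_il4`.
#' @return `write_count_csv` returns `path` invisibly; `read_count_csv`
#'   returns the data frame.
#' @export
write_count_csv <- function(counts, path, layout = NULL, on_state = NULL) {
  out <- counts
  if (!is.null(layout)) {
    stopifnot(nrow(layout) == nrow(counts))
    out$x_um <- layout$x_um
    out$y_um <- layout$y_um
  }
  if (!is.null(on_state)) {
    stopifnot(nrow(on_state) == nrow(counts))
    out$on_ifng <- on_state$on_ifng
    out$on_il4 <- on_state$on_il4
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_csv
#' @export
read_count_csv <- function(path) {
  if (!file.exists(path)) stopf("count table not found: %s", path)
  nf <- tryCatch(count.fields(path, sep = ","), error = function(e) NULL)
  if (!is.null(nf) && length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stopf("malformed CSV %s: line %d has %d fields, expected %d",
          path, bad, nf[bad], nf[1L])
  }
  df <- read.csv(path)
  if (!"cell_id" %in% names(df))
    stopf("malformed count table %s: missing 'cell_id' column", path)
  df
}
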