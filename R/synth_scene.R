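#' Parameters of a synthetic microscopy scene
#'
#' Describes the monolayer geometry and optics used by [make_scene()]:
#' non-overlapping disk-shaped cells of a given diameter, a z-stack with a
#' fixed step, a Gaussian point-spread function for diffraction-limited
#' spots, and additive Gaussian camera noise. Defaults emulate cultured
#' T cells (7 um diameter) imaged at 0.4 um z-spacing; the default spot
#' amplitude over noise sd gives a signal-to-noise ratio of 10.
#'
#' @param n_cells Number of cells to place.
#' @param cell_diameter_um Cell diameter in microns (default 7).
#' @param pixel_size_um Lateral pixel size in microns.
#' @param n_z Number of z-slices.
#' @param z_step_um Z-step in microns (default 0.4).
#' @param psf_sigma_px Lateral Gaussian width of a rendered spot, pixels.
#' @param psf_sigma_z Axial Gaussian width, in z-slices.
#' @param spot_amplitude Peak intensity of a single spot (image units).
#' @param noise_sd Sd of additive Gaussian noise (image units).
#' @param min_sep_px Minimum separation between spots of the same cell, in
#'   pixels (z counted double to reflect the coarser axial sampling);
#'   0 disables the constraint and places spots fully uniformly.
#' @param field_px Optional side length of the square field, pixels;
#'   computed from `n_cells` when `NULL`.
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(n_cells,
                         cell_diameter_um = 7,
                         pixel_size_um = 0.2,
                         n_z = 9,
                         z_step_um = 0.4,
                         psf_sigma_px = 1.5,
                         psf_sigma_z = 1.0,
                         spot_amplitude = 0.1,
                         noise_sd = 0.01,
                         min_sep_px = 0,
                         field_px = NULL,
                         seed = NULL) {
  n_cells <- check_count(n_cells, "n_cells")
  check_number(cell_diameter_um, "cell_diameter_um", 0, strict_lower = TRUE)
  check_number(pixel_size_um, "pixel_size_um", 0, strict_lower = TRUE)
  check_count(n_z, "n_z", lower = 1L)
  check_number(z_step_um, "z_step_um", 0, strict_lower = TRUE)
  check_number(psf_sigma_px, "psf_sigma_px", 0, strict_lower = TRUE)
  check_number(psf_sigma_z, "psf_sigma_z", 0, strict_lower = TRUE)
  check_number(spot_amplitude, "spot_amplitude", 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", 0)
  check_number(min_sep_px, "min_sep_px", 0)
  if (!is.null(field_px)) check_count(field_px, "field_px", lower = 8L)
  if (!is.null(seed)) check_count(seed, "seed")
  structure(
    list(n_cells = n_cells, cell_diameter_um = cell_diameter_um,
         pixel_size_um = pixel_size_um, n_z = as.integer(n_z),
         z_step_um = z_step_um, psf_sigma_px = psf_sigma_px,
         psf_sigma_z = psf_sigma_z, spot_amplitude = spot_amplitude,
         noise_sd = noise_sd, min_sep_px = min_sep_px,
         field_px = field_px, seed = seed),
    class = "scene_params")
}

# dart-throwing placement of non-overlapping disks (touching allowed)
place_centers <- function(n, radius_px, side_px, max_tries = 500L * max(n, 1L)) {
  lo <- radius_px + 2
  hi <- side_px - radius_px - 1
  if (hi <= lo) stopf("field of %d px too small for cells of radius %.1f px",
                      side_px, radius_px)
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n) {
    if (tries >= max_tries)
      stopf("could not place %d non-overlapping cells in a %d px field", n, side_px)
    x <- runif(1, lo, hi); y <- runif(1, lo, hi)
    tries <- tries + 1L
    if (length(cx) == 0 || all((cx - x)^2 + (cy - y)^2 >= (2 * radius_px)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  cbind(x = cx, y = cy)
}

#' Render a synthetic smFISH scene with known ground truth
#'
#' Places `n_cells` non-overlapping disk cells in a monolayer, renders a
#' bright-field reference (dark rim, light interior, so that downstream
#' edge detection finds closed cell boundaries), and renders each
#' transcript of `true_counts` as a 3-D Gaussian spot at a random position
#' inside its cell. Additive Gaussian noise is applied to every channel.
#'
#' @param scene A [scene_params()] object.
#' @param true_counts Data frame or matrix of per-cell integer counts, one
#'   column per gene, `scene$n_cells` rows.
#' @param centers_px Optional `n x 2` matrix of cell centers (x, y in
#'   pixels), e.g. to build touching-cell fixtures; when `NULL`, centers
#'   are placed randomly without overlap (bounded retries, then error).
#' @return A list of class `fish_scene`:
#'   * `channels`: named list of [image_stack()], one per gene;
#'   * `brightfield`: bright-field [image_stack()];
#'   * `truth`: list with `label_mask` (integer matrix), `spots`
#'     (data frame `gene, cell, x, y, z`, pixel coordinates, 1-based),
#'     `true_counts`, `centers_px`, `centers_um`;
#'   * `params`: the scene parameters.
#' @export
make_scene <- function(scene, true_counts, centers_px = NULL) {
  stopifnot(inherits(scene, "scene_params"))
  true_counts <- as.data.frame(true_counts)
  if (nrow(true_counts) != scene$n_cells)
    stopf("true_counts has %d rows but scene$n_cells is %d",
          nrow(true_counts), scene$n_cells)
  genes <- names(true_counts)
  n <- scene$n_cells
  R <- (scene$cell_diameter_um / 2) / scene$pixel_size_um
  side <- scene$field_px %||%
    as.integer(ceiling(ceiling(sqrt(max(n, 1))) * 2.6 * R + 2 * R + 4))
  nz <- scene$n_z

  build <- function() {
    centers <- if (is.null(centers_px)) {
      place_centers(n, R, side)
    } else {
      stopifnot(is.matrix(centers_px), nrow(centers_px) == n)
      centers_px
    }

    # ground-truth label mask: disk of radius R around each center
    labels <- matrix(0L, side, side)
    for (i in seq_len(n)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      xs <- max(1, floor(cx - R)):min(side, ceiling(cx + R))
      ys <- max(1, floor(cy - R)):min(side, ceiling(cy + R))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      sub <- labels[ys, xs]
      sub[d2 <= R^2 & sub == 0L] <- i
      labels[ys, xs] <- sub
    }

    # bright field: mid background, light interior, dark rim of ~2 px
    rim <- 2
    bf1 <- matrix(0.45, side, side)
    for (i in seq_len(n)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      xs <- max(1, floor(cx - R)):min(side, ceiling(cx + R))
      ys <- max(1, floor(cy - R)):min(side, ceiling(cy + R))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      sub <- bf1[ys, xs]
      sub[d2 <= R^2] <- 0.6
      sub[d2 <= R^2 & d2 > (R - rim)^2] <- 0.15
      bf1[ys, xs] <- sub
    }

    sig <- scene$psf_sigma_px
    sigz <- scene$psf_sigma_z
    margin <- 2 * sig + 1
    zlo <- min(1 + sigz, (nz + 1) / 2)
    zhi <- max(nz - sigz, (nz + 1) / 2)
    win <- ceiling(4 * sig)

    place_spots <- function(k, cx, cy) {
      # uniform placement in the cell disk (with a PSF margin), optional
      # minimum-separation constraint via dart throwing
      px <- numeric(k); py <- numeric(k); pz <- numeric(k)
      placed <- 0L
      tries <- 0L
      r_use <- max(R - margin, 1)
      while (placed < k) {
        # best-effort separation: once the retry budget is exhausted the
        # remaining spots are placed unconstrained (a cell too crowded to
        # separate is unresolvable by construction)
        constrain <- scene$min_sep_px > 0 && tries <= 400L * k
        tries <- tries + 1L
        u <- runif(1); ang <- runif(1, 0, 2 * pi)
        rr <- r_use * sqrt(u)
        x <- cx + rr * cos(ang); y <- cy + rr * sin(ang)
        z <- runif(1, zlo, zhi)
        if (constrain && placed > 0L) {
          d <- sqrt((px[1:placed] - x)^2 + (py[1:placed] - y)^2 +
                      (2 * (pz[1:placed] - z))^2)
          if (any(d < scene$min_sep_px)) next
        }
        placed <- placed + 1L
        px[placed] <- x; py[placed] <- y; pz[placed] <- z
      }
      cbind(x = px, y = py, z = pz)
    }

    render_spot <- function(px3, x, y, z, amp) {
      xs <- max(1, floor(x - win)):min(side, ceiling(x + win))
      ys <- max(1, floor(y - win)):min(side, ceiling(y + win))
      g2 <- exp(-outer((ys - y)^2, (xs - x)^2, `+`) / (2 * sig^2))
      for (k in seq_len(nz)) {
        dz <- (k - z) / sigz
        if (abs(dz) > 4) next
        px3[ys, xs, k] <- px3[ys, xs, k] + amp * g2 * exp(-dz^2 / 2)
      }
      px3
    }

    spot_rows <- list()
    channels <- list()
    for (gene in genes) {
      px3 <- array(0, c(side, side, nz))
      for (i in seq_len(n)) {
        k <- as.integer(round(true_counts[[gene]][i]))
        if (k <= 0) next
        pos <- place_spots(k, centers[i, 1], centers[i, 2])
        for (j in seq_len(k))
          px3 <- render_spot(px3, pos[j, 1], pos[j, 2], pos[j, 3],
                             scene$spot_amplitude)
        spot_rows[[length(spot_rows) + 1L]] <-
          data.frame(gene = gene, cell = i,
                     x = pos[, 1], y = pos[, 2], z = pos[, 3])
      }
      channels[[gene]] <- px3
    }

    # additive Gaussian camera noise, clamped at zero
    for (gene in genes) {
      px3 <- channels[[gene]]
      if (scene$noise_sd > 0)
        px3 <- px3 + rnorm(length(px3), 0, scene$noise_sd)
      channels[[gene]] <- pmin(pmax(px3, 0), 1)
    }
    bf <- array(rep(bf1, nz), c(side, side, nz))
    if (scene$noise_sd > 0)
      bf <- bf + rnorm(length(bf), 0, scene$noise_sd)
    bf <- pmin(pmax(bf, 0), 1)

    spots <- if (length(spot_rows)) {
      do.call(rbind, spot_rows)
    } else {
      data.frame(gene = character(0), cell = integer(0),
                 x = numeric(0), y = numeric(0), z = numeric(0))
    }
    list(centers = centers, labels = labels, channels = channels,
         bf = bf, spots = spots)
  }

  b <- with_seed_or_not(scene$seed, build())

  ch <- lapply(genes, function(g)
    image_stack(b$channels[[g]], scene$pixel_size_um, scene$z_step_um, g))
  names(ch) <- genes
  structure(
    list(channels = ch,
         brightfield = image_stack(b$bf, scene$pixel_size_um,
                                   scene$z_step_um, "brightfield"),
         truth = list(label_mask = b$labels,
                      spots = b$spots,
                      true_counts = true_counts,
                      centers_px = b$centers,
                      centers_um = b$centers * scene$pixel_size_um),
         params = scene),
    class = "fish_scene")
}

#' @export
print.fish_scene <- function(x, ...) {
  cat(sprintf("fish_scene: %d cells, %d gene channel(s) [%s], field %d px\n",
              x$params$n_cells, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              nrow(x$truth$label_mask)))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Writes one multi-page TIFF per gene channel plus the bright-field
#' stack, the ground-truth label mask as 16-bit TIFF, and the scene truth
#' (spot coordinates, true counts, centers) as a JSON sidecar.
#'
#' @param x A `fish_scene` from [make_scene()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths, invisibly.
#' @export
write_scene <- function(x, dir) {
  stopifnot(inherits(x, "fish_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (g in names(x$channels)) {
    p <- file.path(dir, paste0(g, ".tif"))
    write_stack(x$channels[[g]], p)
    paths[[g]] <- p
  }
  paths$brightfield <- file.path(dir, "brightfield.tif")
  write_stack(x$brightfield, paths$brightfield)
  paths$label_mask <- file.path(dir, "label_mask.tif")
  write_label_mask(x$truth$label_mask, paths$label_mask)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(spots = x$truth$spots,
         true_counts = x$truth$true_counts,
         centers_um = as.data.frame(x$truth$centers_um),
         pixel_size_um = x$params$pixel_size_um,
         z_step_um = x$params$z_step_um),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Tally ground-truth spots per cell and gene
#'
#' Consistency helper: counts the spots recorded in a scene's truth table
#' per (cell, gene). Equal to `truth$true_counts` by construction.
#'
#' @param truth The `truth` element of a `fish_scene`.
#' @return Data frame of tallies, cells as rows, genes as columns.
#' @export
tally_truth_spots <- function(truth) {
  genes <- names(truth$true_counts)
  n <- nrow(truth$true_counts)
  out <- as.data.frame(matrix(0L, n, length(genes),
                              dimnames = list(NULL, genes)))
  if (nrow(truth$spots)) {
    tab <- table(factor(truth$spots$cell, levels = seq_len(n)),
                 factor(truth$spots$gene, levels = genes))
    out[] <- as.integer(tab)
  }
  out
}
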