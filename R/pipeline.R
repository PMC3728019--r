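# Run configuration and the two end-to-end entry points:
# images -> counts -> report, and counts -> report.

config_defaults <- function() {
  list(
    seed = NULL,
    counts_csv = NULL,
    out_csv = NULL,
    out_json = NULL,
    images = list(
      brightfield = NULL,
      channels = list(),        # gene -> TIFF path
      pixel_size_um = 0.2,
      z_step_um = 0.4
    ),
    segmentation = list(
      min_area_px = 300,
      max_area_px = Inf,
      edge_frac_hi = 0.4,
      edge_frac_lo = 0.2,
      close_radius = 3,
      marker_min_area = 25
    ),
    spots = list(
      sigma_px = 1.5,
      threshold = NULL          # NULL = automatic plateau selection
    ),
    analysis = list(
      ifng_on_threshold = 20,
      il4_on_threshold = 50,
      r_min = 10,
      resolvable_max = 200,
      n_bins = 10,
      no_correlation_cutoff = 0.1
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s",
          paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                 collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && k != "channels") {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build or load a validated run configuration
#'
#' `run_config()` merges user settings into the package defaults and
#' rejects unknown keys; `read_run_config()` does the same from a YAML
#' file. Analysis defaults: Ifng ON threshold 20 transcripts, Il4 ON
#' threshold 50, polar exclusion radius 10, resolvable count maximum 200.
#'
#' @param ... Named settings overriding the defaults; nested sections
#'   (`images`, `segmentation`, `spots`, `analysis`) are given as lists.
#' @param path YAML file path for `read_run_config`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(config_defaults(), user)
  if (!is.null(cfg$seed)) check_count(cfg$seed, "seed")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  do.call(run_config, yaml::read_yaml(path))
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config
  else if (is.character(config) && length(config) == 1L)
    read_run_config(config)
  else do.call(run_config, config)
}

# statistics shared by both pipelines, computed from a count table
counts_report <- function(df, analysis) {
  rep <- list()
  genes <- intersect(c("tbx21", "gata3", "ifng", "il4"), names(df))
  rep$n_cells <- nrow(df)
  rep$mean_counts <- lapply(df[genes], mean)

  if (all(c("tbx21", "gata3") %in% genes)) {
    pol <- to_polar(df$tbx21, df$gata3)
    fr <- filter_r(pol, r_min = analysis$r_min)
    if (nrow(fr$kept) > 0) {
      ts <- theta_summary(fr$kept$theta, n_bins = analysis$n_bins,
                          n_excluded = fr$n_excluded)
      ut <- uniformity_test(fr$kept$theta)
      rep$polar <- list(
        n_kept = ts$n_kept, n_excluded = ts$n_excluded,
        median_theta = ts$median_theta, u_index = ts$u_index,
        hist_breaks = ts$hist$breaks, hist_density = ts$hist$density,
        uniformity_D = ut$D, uniformity_p = ut$p,
        consistent_with_uniform = ut$p > 0.01,
        u_shaped = ts$u_index > 0.75)
    }
  }

  thr <- list(ifng = analysis$ifng_on_threshold,
              il4 = analysis$il4_on_threshold)
  for (cy in intersect(c("ifng", "il4"), genes)) {
    cyrep <- list(on_fraction = on_fraction(df[[cy]], thr[[cy]]))
    fit <- tryCatch(fit_gamma(df[[cy]], on_threshold = 0),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      cyrep$gamma_shape <- fit$shape
      cyrep$gamma_scale <- fit$scale
      cyrep$burst_size <- burst_size(fit)
      cyrep$n_fit <- fit$n_fit
    }
    tf <- if (cy == "ifng") "tbx21" else "gata3"
    if (tf %in% genes) {
      pc <- tryCatch(pearson_cor(df[[tf]], df[[cy]]),
                     error = function(e) NULL)
      if (!is.null(pc)) cyrep$tf_correlation <- pc
      ci <- tryCatch(
        suppressWarnings(conditional_invariance(df[[tf]], df[[cy]])),
        error = function(e) NULL)
      if (!is.null(ci))
        cyrep$conditional_invariance <- list(
          max_D = ci$max_D, min_p_adj = ci$min_p_adj,
          invariant = ci$min_p_adj > 0.01)
      if (all(c("x_um", "y_um") %in% names(df))) {
        dist <- tryCatch(
          nearest_producer_distance(df$x_um, df$y_um, df[[cy]], thr[[cy]]),
          error = function(e) NULL)
        if (!is.null(dist)) {
          dc <- tryCatch(
            distance_correlation_check(df[[tf]], dist,
                                       analysis$no_correlation_cutoff),
            error = function(e) NULL)
          if (!is.null(dc)) cyrep$distance_correlation <- dc
        }
      }
    }
    rep[[cy]] <- cyrep
  }
  rep
}

write_report <- function(report, path) {
  if (is.null(path)) return(invisible(NULL))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Analyze an existing per-cell count table
#'
#' Runs the polar-coordinate, burst-inference and population statistics
#' on a count table CSV (columns `cell_id, tbx21, gata3, ifng, il4`,
#' optionally `x_um, y_um`): theta distribution with uniformity test,
#' ON-cell fractions, Gamma burst fits, TF-cytokine correlations,
#' conditional-invariance checks and nearest-producer distance
#' correlations. The report is deterministic given the configuration.
#'
#' @param config A `run_config`, a YAML path, or a named list of
#'   settings; `counts_csv` must point at the count table.
#' @return The report as a nested list (invisibly written to
#'   `config$out_json` when set).
#' @export
run_counts_pipeline <- function(config) {
  cfg <- as_run_config(config)
  if (is.null(cfg$counts_csv)) stopf("config$counts_csv is not set")
  df <- read_count_csv(cfg$counts_csv)
  if (nrow(df) == 0) stopf("count table %s is empty", cfg$counts_csv)
  report <- list(
    config = list(counts_csv = cfg$counts_csv, analysis = cfg$analysis),
    stats = counts_report(df, cfg$analysis))
  write_report(report, cfg$out_json)
  report
}

#' Quantify image stacks into per-cell counts and analyze them
#'
#' Full image pipeline: segment cells from the bright-field stack,
#' auto-select (or take) the spot-detection threshold per FISH channel,
#' detect and assign spots, quantify background-subtracted fluorescence,
#' extrapolate unresolvable high expressers from the fluorescence
#' calibration, then run every count-level statistic. Stage parameters
#' are recorded in the report.
#'
#' @param config As in [run_counts_pipeline()]; `images$brightfield` and
#'   `images$channels` (named gene -> TIFF path) are required.
#' @return List with `cells` (the per-cell data frame, written to
#'   `config$out_csv` when set) and `report`.
#' @export
run_image_pipeline <- function(config) {
  cfg <- as_run_config(config)
  img <- cfg$images
  if (is.null(img$brightfield)) stopf("config$images$brightfield is not set")
  if (length(img$channels) == 0) stopf("config$images$channels is empty")
  for (p in c(img$brightfield, unlist(img$channels)))
    if (!file.exists(p)) stopf("input image not found: %s", p)

  bf <- read_stack(img$brightfield, img$pixel_size_um, img$z_step_um,
                   "brightfield")
  seg <- cfg$segmentation
  mask <- segment_cells(bf,
                        min_area_px = seg$min_area_px,
                        max_area_px = seg$max_area_px,
                        edge_frac_hi = seg$edge_frac_hi,
                        edge_frac_lo = seg$edge_frac_lo,
                        close_radius = seg$close_radius,
                        marker_min_area = seg$marker_min_area)
  cells <- mask_table(mask)
  stages <- list(segmentation = c(seg, n_cells = nrow(cells)))

  for (gene in names(img$channels)) {
    ch <- read_stack(img$channels[[gene]], img$pixel_size_um,
                     img$z_step_um, gene)
    thr <- cfg$spots$threshold %||%
      select_threshold(ch, sigma_px = cfg$spots$sigma_px)
    spots <- detect_spots(ch, sigma_px = cfg$spots$sigma_px,
                          threshold = as.numeric(thr))
    asg <- assign_spots(spots, mask)
    fl <- quantify_fluorescence(ch, mask)
    cells[[paste0(gene, "_count")]] <- asg$counts$count
    cells[[paste0(gene, "_fluor")]] <- fl$total_fluor
    stages[[paste0("spots_", gene)]] <-
      list(sigma_px = cfg$spots$sigma_px, threshold = as.numeric(thr),
           n_spots = nrow(spots), n_background = asg$n_background)
    ext <- tryCatch(
      extrapolate_counts(cells, paste0(gene, "_count"),
                         paste0(gene, "_fluor"),
                         resolvable_max = cfg$analysis$resolvable_max),
      error = function(e) NULL)
    if (!is.null(ext)) {
      cells <- ext
      stages[[paste0("extrapolation_", gene)]] <-
        list(slope = attr(ext, "slope"),
             n_calibration = attr(ext, "n_calibration"))
    }
  }

  # count-level statistics on the quantified table
  stat_df <- cells[, c("cell_id", "x_um", "y_um"), drop = FALSE]
  for (gene in names(img$channels))
    stat_df[[gene]] <- cells[[paste0(gene, "_count")]]
  report <- list(
    config = list(images = img, segmentation = seg, spots = cfg$spots,
                  analysis = cfg$analysis, seed = cfg$seed),
    stages = stages,
    stats = counts_report(stat_df, cfg$analysis))

  if (!is.null(cfg$out_csv)) {
    dir.create(dirname(cfg$out_csv), recursive = TRUE, showWarnings = FALSE)
    write.csv(cells, cfg$out_csv, row.names = FALSE)
  }
  write_report(report, cfg$out_json)
  list(cells = cells, report = report)
}
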