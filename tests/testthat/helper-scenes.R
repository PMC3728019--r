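# shared fixture builders: small planted-truth scenes and the mapping
# from segmented labels back to ground-truth cells

make_test_scene <- function(n_cells, counts_range = 3:10, seed = 11,
                            n_z = 9, min_sep_px = 7, genes = c("tbx21", "gata3"),
                            ...) {
  withr::with_seed(seed, {
    cnts <- as.data.frame(lapply(genes, function(g)
      counts_range[sample.int(length(counts_range), n_cells, replace = TRUE)]))
    names(cnts) <- genes
    sc <- make_scene(scene_params(n_cells, n_z = n_z,
                                  min_sep_px = min_sep_px, seed = seed + 1,
                                  ...), cnts)
    list(scene = sc, counts = cnts)
  })
}

# map segmented cell ids to ground-truth cell ids via the segment centroid
truth_label_of <- function(mask, truth_labels) {
  mt <- mask_table(mask)
  truth_labels[cbind(round(mt$y_px), round(mt$x_px))]
}

# per-truth-cell best intersection-over-union achieved by any segment
iou_per_cell <- function(mask, truth_labels, n_cells) {
  vapply(seq_len(n_cells), function(i) {
    t_i <- truth_labels == i
    labs <- setdiff(unique(mask$labels[t_i]), 0L)
    if (!length(labs)) return(0)
    max(vapply(labs, function(l) {
      s_l <- mask$labels == l
      sum(t_i & s_l) / sum(t_i | s_l)
    }, numeric(1)))
  }, numeric(1))
}

# fraction of cells whose recovered count equals the planted count
exact_count_fraction <- function(scene, counts, gene, mask = NULL) {
  mask <- mask %||% segment_cells(scene$brightfield)
  ch <- scene$channels[[gene]]
  thr <- suppressWarnings(select_threshold(ch))
  spots <- detect_spots(ch, threshold = as.numeric(thr))
  asg <- assign_spots(spots, mask)
  tl <- truth_label_of(mask, scene$truth$label_mask)
  got <- asg$counts$count
  ok <- !is.na(tl) & tl > 0
  mean(got[ok] == counts[[gene]][tl[ok]]) * (sum(ok) / nrow(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
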