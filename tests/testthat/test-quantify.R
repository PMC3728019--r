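test_that("spots are assigned to the cell under them; background reported", {
  labels <- matrix(0L, 20, 20)
  labels[3:8, 3:8] <- 1L
  labels[12:18, 12:18] <- 2L
  sp <- data.frame(y = c(4, 5, 6, 15), x = c(4, 5, 6, 15),
                   z = 1, peak = 1, n_voxels = 1)
  asg <- assign_spots(sp, labels)
  expect_equal(asg$counts$count, c(3L, 1L))
  expect_equal(asg$n_background, 0L)

  sp2 <- rbind(sp, data.frame(y = 1, x = 1, z = 1, peak = 1, n_voxels = 1))
  asg2 <- assign_spots(sp2, labels)
  expect_equal(asg2$counts$count, c(3L, 1L))
  expect_equal(asg2$n_background, 1L)
})

test_that("planted scenes give per-cell counts equal to the truth", {
  ts <- make_test_scene(8, counts_range = 3:9, seed = 101)
  mask <- segment_cells(ts$scene$brightfield)
  frac <- exact_count_fraction(ts$scene, ts$counts, "tbx21", mask)
  expect_gte(frac, 0.95)
})

test_that("fluorescence quantification follows its defining algebra", {
  labels <- matrix(0L, 30, 30)
  labels[2:11, 2:11] <- 1L    # 100 px
  labels[15:24, 15:24] <- 2L  # 100 px
  base <- array(0.2, c(30, 30, 1))

  # uniform image: background equals every mean, all totals zero
  fl <- quantify_fluorescence(image_stack(base, 0.2), labels)
  expect_equal(fl$total_fluor, c(0, 0))

  # one cell brighter by delta: its total is area * delta, other 0
  bright <- base
  bright[2:11, 2:11, 1] <- 0.2 + 0.003
  fl2 <- quantify_fluorescence(image_stack(bright, 0.2), labels)
  expect_equal(fl2$total_fluor, c(100 * 0.003, 0), tolerance = 1e-10)

  # adding a constant to the whole image changes nothing
  fl3 <- quantify_fluorescence(image_stack(bright + 0.1, 0.2), labels)
  expect_equal(fl3$total_fluor, fl2$total_fluor, tolerance = 1e-10)

  # clamped at zero for any input
  withr::with_seed(8, {
    rnd <- array(runif(30 * 30, 0, 0.4), c(30, 30, 1))
    fl4 <- quantify_fluorescence(image_stack(rnd, 0.2), labels)
    expect_true(all(fl4$total_fluor >= 0))
  })

  # empty mask: empty result, no error
  expect_equal(nrow(quantify_fluorescence(image_stack(base, 0.2),
                                          matrix(0L, 30, 30))), 0)
})

test_that("extrapolation inverts an exactly linear calibration", {
  s <- 2.5
  cells <- data.frame(count = c(1, 5, 20, 80, 150, 300),
                      fluor = s * c(1, 5, 20, 80, 150, 1000))
  out <- extrapolate_counts(cells, "count", "fluor")
  expect_equal(attr(out, "slope"), s, tolerance = 1e-12)
  expect_equal(out$count[6], 1000, tolerance = 1e-9)
  expect_equal(out$count[1:5], cells$count[1:5])

  # nothing above the resolvable range: table unchanged
  low <- data.frame(count = c(2, 7, 9, 12, 40, 80),
                    fluor = s * c(2, 7, 9, 12, 40, 80))
  expect_equal(extrapolate_counts(low, "count", "fluor")$count, low$count)

  expect_error(
    extrapolate_counts(data.frame(count = c(1, 2, 300), fluor = c(1, 2, 3)),
                       "count", "fluor"),
    "calibration")
})
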