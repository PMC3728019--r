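test_that("blank stacks yield no spots and a warned fallback threshold", {
  blank <- image_stack(array(0, c(40, 40, 5)), 0.2)
  expect_equal(nrow(detect_spots(blank, threshold = 0.01)), 0)
  expect_warning(thr <- select_threshold(blank), "threshold|plateau")
  expect_gt(as.numeric(thr), 0)
  expect_equal(nrow(detect_spots(blank, threshold = as.numeric(thr))), 0)
  expect_error(detect_spots(blank, threshold = 0), "threshold")
  expect_error(detect_spots(blank, threshold = -1), "threshold")
})

test_that("planted spots are each recovered once, within one pixel", {
  ts <- make_test_scene(1, counts_range = 10:10, seed = 71, genes = "tbx21")
  ch <- ts$scene$channels$tbx21
  thr <- select_threshold(ch)
  sp <- detect_spots(ch, threshold = as.numeric(thr))
  expect_equal(nrow(sp), 10)
  truth <- ts$scene$truth$spots
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((sp$x - truth$x[i])^2 + (sp$y - truth$y[i])^2)
    expect_lte(min(d), 1.5)
  }
  # a threshold above every LoG peak finds nothing
  expect_equal(nrow(detect_spots(ch, threshold = max(sp$peak) * 1.01)), 0)
})

test_that("auto threshold sits on a plateau of the count curve", {
  ts <- make_test_scene(3, counts_range = 4:8, seed = 81, genes = "tbx21")
  ch <- ts$scene$channels$tbx21
  thr <- select_threshold(ch)
  n0 <- attr(thr, "plateau_count")
  expect_equal(n0, sum(ts$counts$tbx21))
  # the same count holds across the plateau neighborhood
  for (f in c(0.8, 1, 1.25))
    expect_equal(nrow(detect_spots(ch, threshold = as.numeric(thr) * f)), n0)
})

test_that("threshold selection is equivariant to intensity scaling", {
  ts <- make_test_scene(2, counts_range = 4:6, seed = 91, genes = "tbx21")
  ch <- ts$scene$channels$tbx21
  ch2 <- image_stack(ch$pixels * 0.5, ch$pixel_size_um, ch$z_step_um,
                     ch$channel)
  t1 <- select_threshold(ch)
  t2 <- select_threshold(ch2)
  expect_equal(as.numeric(t2) / as.numeric(t1), 0.5, tolerance = 1e-8)
  expect_equal(nrow(detect_spots(ch, threshold = as.numeric(t1))),
               nrow(detect_spots(ch2, threshold = as.numeric(t2))))
})

test_that("a spot spanning several z-slices is counted once", {
  # single bright 3-D Gaussian centered between two slices
  px <- array(0, c(31, 31, 6))
  for (k in 1:6)
    px[, , k] <- 0.2 * exp(-(outer((1:31 - 16)^2, (1:31 - 16)^2, `+`)) /
                             (2 * 1.5^2)) * exp(-(k - 3.5)^2 / 2)
  st <- image_stack(px, 0.2)
  sp <- detect_spots(st, threshold = 0.005)
  expect_equal(nrow(sp), 1)
  expect_gte(sp$n_voxels, 2)
})
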