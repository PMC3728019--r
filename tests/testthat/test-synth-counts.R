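test_that("degenerate parameters give degenerate tables", {
  tab <- make_count_table(regime_params(p_on_ifng = 0, seed = 1), 500)
  expect_true(all(tab$counts$ifng == 0))
  expect_false(any(tab$on_state$on_ifng))

  empty <- make_count_table(regime_params(seed = 1), 0)
  expect_equal(nrow(empty$counts), 0)

  expect_error(make_count_table(regime_params(seed = 1), -1), "n_cells")
  expect_error(regime_params(p_on_ifng = 1.5), "p_on_ifng")
  expect_error(regime_params(burst_scale_ifng = 0), "burst_scale_ifng")
})

test_that("the generator is a pure function of its seed", {
  a <- make_count_table(regime_params(seed = 42), 300)
  b <- make_count_table(regime_params(seed = 42), 300)
  c <- make_count_table(regime_params(seed = 43), 300)
  expect_identical(a$counts, b$counts)
  expect_identical(a$on_state, b$on_state)
  expect_false(identical(a$counts, c$counts))
})

test_that("ON-cell cytokine counts have the configured Gamma mean", {
  # every cell ON so the sample is pure Gamma(1, 159); 3-standard-error band
  n <- 50000
  tab <- make_count_table(regime_params(p_on_ifng = 1, seed = 5), n)
  se <- 159 / sqrt(n)
  expect_lt(abs(mean(tab$counts$ifng) - 159), 3 * se)
})

test_that("mixed-regime angles are uniform on [0, pi/2]", {
  tab <- make_count_table(regime_params(seed = 7), 50000)
  keep <- tab$latent$r >= 10
  ks <- uniformity_test(tab$latent$theta[keep])
  expect_gt(ks$p, 0.01)
})

test_that("the exclusive regime concentrates angles at the axes", {
  spread <- function(regime, seed) {
    tab <- make_count_table(regime_params(regime = regime, seed = seed), 10000)
    median(abs(tab$latent$theta - pi / 4))
  }
  for (seed in 1:3)
    expect_gt(spread("exclusive", seed), spread("mixed", seed))
})

test_that("count tables survive a CSV round trip", {
  tab <- make_count_table(regime_params(seed = 3), 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_csv(tab$counts, path, on_state = tab$on_state)
  back <- read_count_csv(path)
  expect_equal(back$tbx21, tab$counts$tbx21)
  expect_equal(back$on_ifng, tab$on_state$on_ifng)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,tbx21", "1,2", "2,3,4"), bad)
  expect_error(read_count_csv(bad), "line 3")
})
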