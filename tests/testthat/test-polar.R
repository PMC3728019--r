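test_that("polar conversion matches hand-computed cases", {
  p <- to_polar(c(10, 30, 0, 6, 0), c(10, 0, 20, 8, 0))
  expect_equal(p$r, c(sqrt(200), 30, 20, 10, 0))
  expect_equal(p$theta, c(pi / 4, 0, pi / 2, atan(4 / 3), 0))
  expect_error(to_polar(-1, 2), "non-negative")
})

test_that("polar conversion round-trips and is scale-equivariant", {
  withr::with_seed(12, {
    t <- rexp(200, 1 / 40)
    g <- rexp(200, 1 / 40)
  })
  p <- to_polar(t, g)
  expect_equal(p$r * cos(p$theta), t, tolerance = 1e-9)
  expect_equal(p$r * sin(p$theta), g, tolerance = 1e-9)
  p3 <- to_polar(3 * t, 3 * g)
  expect_equal(p3$r, 3 * p$r, tolerance = 1e-12)
  expect_equal(p3$theta, p$theta, tolerance = 1e-12)
})

test_that("the low-count exclusion rule is strict at the boundary", {
  p <- to_polar(c(3, 6, 0), c(4, 8, 0))  # r = 5, 10, 0
  fr <- filter_r(p)
  expect_equal(fr$kept$r, 10)
  expect_equal(fr$n_excluded, 2)
  fr0 <- filter_r(p, r_min = 0)
  expect_equal(nrow(fr0$kept), 3)
})

test_that("theta summaries report median, histogram and U-shape index", {
  s <- theta_summary(rep(pi / 4, 50))
  expect_equal(s$median_theta, pi / 4)
  expect_equal(s$u_index, 0)

  s2 <- theta_summary(rep(c(0, pi / 2), 25))
  expect_equal(s2$u_index, 1)

  withr::with_seed(3, u <- runif(10000, 0, pi / 2))
  s3 <- theta_summary(u)
  expect_lt(abs(s3$median_theta - pi / 4), 0.02)
  # densities integrate to one
  widths <- diff(s3$hist$breaks)
  expect_equal(sum(s3$hist$density * widths), 1, tolerance = 1e-9)

  expect_error(theta_summary(numeric(0)), "empty")
  expect_error(theta_summary(c(0.1, 2)), "pi/2")
})

test_that("two-sample KS matches enumerated ECDF cases", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$D, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("the uniformity test matches its closed-form cases", {
  # mid-grid construction: D = 1/(2n)
  n <- 50
  grid <- (seq_len(n) - 0.5) / n * (pi / 2)
  expect_equal(uniformity_test(grid)$D, 1 / (2 * n), tolerance = 1e-12)

  # a point mass at pi/4 gives D = 0.5 and a vanishing p-value
  ut <- uniformity_test(rep(pi / 4, 100))
  expect_equal(ut$D, 0.5)
  expect_lt(ut$p, 1e-6)

  withr::with_seed(4, u <- runif(5000, 0, pi / 2))
  expect_gt(uniformity_test(u)$p, 0.01)
  expect_error(uniformity_test(c(-0.1, 1)), "pi/2")
})
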