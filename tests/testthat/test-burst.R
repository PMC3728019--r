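test_that("simulator argument contracts hold", {
  expect_true(all(simulate_two_state(1, 2, 0, 1, 100, seed = 1) == 0))
  expect_error(simulate_two_state(0, 2, 5, 1, 10), "k_on")
  expect_error(simulate_two_state(1, -2, 5, 1, 10), "k_off")
  expect_identical(simulate_two_state(1, 2, 30, 1, 200, seed = 5),
                   simulate_two_state(1, 2, 30, 1, 200, seed = 5))
})

test_that("simulated mean matches the closed-form stationary mean", {
  k_on <- 1; k_off <- 2; k_tx <- 30; k_deg <- 1
  cnt <- simulate_two_state(k_on, k_off, k_tx, k_deg, 5000, seed = 1)
  mu <- two_state_mean(k_on, k_off, k_tx, k_deg)
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - mu), 3 * se)
})

test_that("bursty-limit counts follow the Gamma law", {
  # k_off = 100 k_deg, k_on = k_deg, burst size k_tx / k_off = 20;
  # tested at a sample size where KS resolution exceeds the irreducible
  # discrete-continuous zero-class gap
  cnt <- simulate_two_state(1, 100, 2000, 1, 300, seed = 1)
  kt <- suppressWarnings(ks.test(cnt, pgamma, shape = 1, scale = 20))
  expect_gt(kt$p.value, 0.01)
})

test_that("Gillespie agrees with the truncated master equation", {
  k_on <- 1; k_off <- 2; k_tx <- 30; k_deg <- 1
  pmf <- two_state_pmf(k_on, k_off, k_tx, k_deg)
  expect_equal(sum(pmf), 1, tolerance = 1e-9)
  expect_equal(sum(pmf * (seq_along(pmf) - 1)),
               two_state_mean(k_on, k_off, k_tx, k_deg), tolerance = 1e-6)
  cnt <- simulate_two_state(k_on, k_off, k_tx, k_deg, 50000, seed = 2)
  emp <- tabulate(cnt + 1L, nbins = length(pmf)) / length(cnt)
  tvd <- 0.5 * (sum(abs(emp - pmf)) + max(0, 1 - sum(emp)))
  expect_lte(tvd, 0.02)
})

test_that("Gamma MLE recovers parameters of continuous Gamma draws", {
  withr::with_seed(6, x <- rgamma(5000, shape = 2, scale = 50))
  fit <- fit_gamma(x)
  expect_lt(abs(fit$scale - 50) / 50, 0.05)
  expect_lt(abs(fit$shape - 2) / 2, 0.05)
  # method-of-moments oracle agrees with the MLE on this sample
  mom_shape <- mean(x)^2 / var(x)
  mom_scale <- var(x) / mean(x)
  expect_lt(abs(fit$shape - mom_shape) / mom_shape, 0.1)
  expect_lt(abs(fit$scale - mom_scale) / mom_scale, 0.1)
})

test_that("fitted shape * scale equals the sample mean exactly", {
  for (seed in 1:5) {
    withr::with_seed(seed, x <- rgamma(500, shape = runif(1, 0.5, 3),
                                       scale = runif(1, 5, 200)))
    fit <- fit_gamma(x)
    expect_equal(fit$shape * fit$scale, mean(x), tolerance = 1e-6)
  }
})

test_that("degenerate samples are rejected", {
  expect_error(fit_gamma(rep(5, 100)), "equal")
  expect_error(fit_gamma(c(1, 2, 3)), ">= 20")
  expect_error(fit_gamma(1:30, include_zero = TRUE), "continuity")
})

test_that("the fit is scale-equivariant", {
  withr::with_seed(7, x <- rgamma(2000, shape = 1, scale = 40))
  f1 <- fit_gamma(x)
  f2 <- fit_gamma(3 * x)
  expect_equal(f2$scale / f1$scale, 3, tolerance = 1e-8)
  expect_equal(f2$shape, f1$shape, tolerance = 1e-8)
})

test_that("scale recovery holds across the parameter grid", {
  # median relative error of the fitted scale <= 5% at n = 5000
  for (shape in c(0.5, 1, 2)) {
    for (scale in c(18, 36, 159, 176)) {
      errs <- vapply(1:20, function(seed) {
        withr::with_seed(1000 * shape + seed,
                         x <- rgamma(5000, shape = shape, scale = scale))
        abs(fit_gamma(x)$scale - scale) / scale
      }, numeric(1))
      expect_lte(median(errs), 0.05)
    }
  }
})

test_that("burst_size reads the fitted scale", {
  withr::with_seed(9, x <- rgamma(1000, shape = 1, scale = 159))
  fit <- fit_gamma(x)
  expect_identical(burst_size(fit), fit$scale)
  fit$scale <- 159
  expect_equal(burst_size(fit), 159)
})

test_that("burst size is recovered from a bursty-limit simulation", {
  # k_tx / k_off = 36; recovery within 10%
  cnt <- simulate_two_state(1, 100, 3600, 1, 5000, seed = 3)
  fit <- fit_gamma(cnt, continuity = TRUE, include_zero = TRUE)
  expect_lt(abs(burst_size(fit) - 36) / 36, 0.1)
})
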