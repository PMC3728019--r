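test_that("ON fractions use a strict threshold", {
  expect_equal(on_fraction(c(0, 0, 25, 100, 5), 20), 0.4)
  expect_equal(on_fraction(c(10, 20, 30), 20), 1 / 3)  # exactly 20 is OFF
  expect_equal(on_fraction(rep(0, 10), 20), 0)
  expect_error(on_fraction(numeric(0), 20), "empty")
})

test_that("ON fraction is monotone non-increasing in the threshold", {
  withr::with_seed(11, counts <- rpois(500, 30))
  fr <- vapply(seq(0, 100, 5), function(t) on_fraction(counts, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("percent reductions reproduce the knockout comparisons", {
  expect_equal(as.numeric(percent_reduction(33, 1.6)), 95)
  expect_equal(as.numeric(percent_reduction(35, 2.3)), 93)
  expect_equal(as.numeric(percent_reduction(12, 12)), 0)
  expect_equal(as.numeric(percent_reduction(7, 0)), 100)
  # invariant to rescaling both means
  expect_equal(attr(percent_reduction(33, 1.6), "raw"),
               attr(percent_reduction(330, 16), "raw"))
  expect_error(percent_reduction(0, 1), "mean_ref")
})

test_that("Pearson correlation matches the covariance-formula oracle", {
  expect_equal(pearson_cor(1:10, 1:10)$R, 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2))$R, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y)$R, oracle, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_cor(1:2, 1:2), "3")
})

test_that("nearest-producer distances match the brute-force oracle", {
  # 3-4-5 triangle
  d <- nearest_producer_distance(c(0, 3), c(0, 4), c(100, 0), 20)
  expect_equal(d, c(0, 5))

  withr::with_seed(13, {
    n <- 400
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    counts <- ifelse(runif(n) < 0.05, 100, 0)
  })
  got <- nearest_producer_distance(x, y, counts, 20)
  prod <- which(counts > 20)
  oracle <- vapply(seq_len(n), function(i)
    min(sqrt((x[i] - x[prod])^2 + (y[i] - y[prod])^2)), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got[prod] == 0))
  expect_error(nearest_producer_distance(x, y, rep(0, n), 20), "producer")
})

test_that("distance-independent expression reports no correlation", {
  ok <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 5000
      x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
      counts <- ifelse(runif(n) < 0.03, 200, 0)
      tf <- rpois(n, 30)
    })
    d <- nearest_producer_distance(x, y, counts, 20)
    distance_correlation_check(tf, d)$uncorrelated
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("a real distance dependence is detected as negative", {
  withr::with_seed(17, {
    n <- 500
    x <- runif(n, 0, 300); y <- runif(n, 0, 300)
    counts <- ifelse(runif(n) < 0.05, 100, 0)
  })
  d <- nearest_producer_distance(x, y, counts, 20)
  tf <- 100 - 0.5 * d
  res <- distance_correlation_check(tf, d)
  expect_lt(res$R, 0)
  expect_false(res$uncorrelated)
  expect_error(distance_correlation_check(rep(5, n), d), "constant")
})

test_that("conditional invariance holds under the null and breaks under a shift", {
  null_ok <- vapply(1:20, function(seed) {
    withr::with_seed(seed, {
      n <- 2000
      tf <- rpois(n, 35)
      cyto <- ifelse(runif(n) < 0.2, rgamma(n, 1, scale = 150), 0)
    })
    ci <- suppressWarnings(conditional_invariance(tf, cyto))
    ci$min_p_adj > 0.01
  }, logical(1))
  expect_gte(mean(null_ok), 0.95)

  withr::with_seed(30, {
    n <- 2000
    tf <- rpois(n, 35)
    cyto <- ifelse(runif(n) < 0.2, rgamma(n, 1, scale = 150), 0)
    tf[cyto >= 100] <- tf[cyto >= 100] + 50
  })
  ci <- suppressWarnings(conditional_invariance(tf, cyto))
  expect_lt(ci$min_p_adj, 0.01)

  # identical strata: all D zero
  tf2 <- rep(c(10, 20, 30, 40), 50)
  cyto2 <- rep(c(0, 30), each = 100)
  ci2 <- suppressWarnings(conditional_invariance(tf2, cyto2))
  expect_equal(ci2$max_D, 0)
})

test_that("time-course fraction/TF correlation behaves", {
  expect_equal(timecourse_fraction_tf_correlation(c(0.1, 0.2, 0.3),
                                                  c(10, 20, 30))$R, 1)
  f <- c(0.05, 0.12, 0.09, 0.2)
  m <- c(12, 30, 22, 41)
  oracle <- cor(f, m)
  expect_equal(timecourse_fraction_tf_correlation(f, m)$R, oracle)
  expect_error(timecourse_fraction_tf_correlation(c(0.1, 0.2), c(1, 2)), "3")
  expect_error(timecourse_fraction_tf_correlation(rep(0.1, 4), 1:4), "constant")
})
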