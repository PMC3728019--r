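#' Simulate steady-state mRNA counts under the two-state model
#'
#' Exact stochastic (Gillespie) simulation of the telegraph model of
#' transcription: a promoter switches OFF -> ON at rate `k_on` and
#' ON -> OFF at rate `k_off`; mRNA is made at rate `k_tx` while ON and
#' degraded at rate `k_deg` per molecule. Each cell is simulated
#' independently for a burn-in of at least ten mRNA lifetimes before the
#' copy number is sampled, which is ample for both the promoter and the
#' mRNA pool to relax to stationarity.
#'
#' In the bursty limit (`k_off >> k_on`, `k_off >> k_deg`) the promoter
#' fires short bursts of geometric size with mean `k_tx / k_off`, and the
#' stationary copy-number density approaches a Gamma distribution with
#' shape `k_on / k_deg` (bursts per mRNA lifetime) and scale
#' `k_tx / k_off` (mean burst size).
#'
#' @param k_on,k_off,k_deg Positive rates; `k_tx` may be zero (no
#'   transcription, all counts zero).
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed, or `NULL`.
#' @param burn_in Simulated time before sampling; default `10 / k_deg`.
#' @return Integer vector of `n_cells` steady-state counts.
#' @seealso [two_state_mean()], [two_state_pmf()], [fit_gamma()]
#' @export
simulate_two_state <- function(k_on, k_off, k_tx, k_deg, n_cells,
                               seed = NULL, burn_in = NULL) {
  for (nm in c("k_on", "k_off", "k_deg"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(k_tx, "k_tx", lower = 0)
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  burn_in <- burn_in %||% (10 / k_deg)
  check_number(burn_in, "burn_in", lower = 0, strict_lower = TRUE)
  with_seed_or_not(seed,
    .ssa_two_state(n_cells, k_on, k_off, k_tx, k_deg, burn_in))
}

#' Closed-form stationary mean of the two-state model
#'
#' `k_tx * k_on / (k_deg * (k_on + k_off))`: transcription rate times the
#' stationary ON probability, divided by the degradation rate.
#'
#' @inheritParams simulate_two_state
#' @return The stationary mean copy number.
#' @export
two_state_mean <- function(k_on, k_off, k_tx, k_deg) {
  k_tx * k_on / (k_deg * (k_on + k_off))
}

#' Stationary count distribution by the truncated master equation
#'
#' Independent numerical route to the stationary law of the telegraph
#' model: the chemical master equation on the state space
#' promoter x {0, ..., m_max} is assembled as a sparse generator and its
#' stationary distribution solved as a linear system. Used to cross-check
#' the stochastic simulator.
#'
#' @inheritParams simulate_two_state
#' @param m_max Truncation bound; by default the mean plus twelve times
#'   an overdispersed standard deviation.
#' @return Numeric vector `p[m+1] = P(count = m)` for `m = 0..m_max`,
#'   marginal over the promoter state.
#' @export
two_state_pmf <- function(k_on, k_off, k_tx, k_deg, m_max = NULL) {
  for (nm in c("k_on", "k_off", "k_deg"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(k_tx, "k_tx", lower = 0)
  mu <- two_state_mean(k_on, k_off, k_tx, k_deg)
  if (is.null(m_max)) {
    fano <- 1 + k_tx * k_off /
      ((k_on + k_off) * (k_on + k_off + k_deg))
    m_max <- ceiling(mu + 12 * sqrt(max(mu * fano, 1)))
  }
  m_max <- check_count(m_max, "m_max", lower = 1L)

  # state index: promoter s in {0 (OFF), 1 (ON)}, count m in 0..m_max
  id <- function(s, m) s * (m_max + 1L) + m + 1L
  ns <- 2L * (m_max + 1L)
  i <- integer(0); j <- integer(0); v <- numeric(0)
  add <- function(from, to, rate) {
    i <<- c(i, from); j <<- c(j, to); v <<- c(v, rate)
  }
  for (m in 0:m_max) {
    add(id(0L, m), id(1L, m), k_on)
    add(id(1L, m), id(0L, m), k_off)
    if (m < m_max) add(id(1L, m), id(1L, m + 1L), k_tx)
    if (m > 0) {
      add(id(0L, m), id(0L, m - 1L), m * k_deg)
      add(id(1L, m), id(1L, m - 1L), m * k_deg)
    }
  }
  Q <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(ns, ns))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # stationary law: p' Q = 0 with sum(p) = 1, solved in least squares
  A <- rbind(Matrix::t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  p <- as.numeric(Matrix::solve(Matrix::crossprod(A),
                                Matrix::crossprod(A, b)))
  p <- pmax(p, 0); p <- p / sum(p)
  p[1:(m_max + 1L)] + p[(m_max + 2L):ns]
}

#' Maximum-likelihood Gamma fit to ON-cell transcript counts
#'
#' Fits a Gamma distribution to the counts above `on_threshold`, treating
#' the integer counts as continuous observations (no continuity
#' correction; zeros are excluded by the default threshold). The shape is
#' found by Newton iteration on the profile likelihood equation
#' `log(a) - digamma(a) = log(mean(x)) - mean(log(x))`, started from the
#' standard closed-form approximation; the scale is `mean(x) / shape`,
#' so the fitted mean equals the sample mean exactly (the Gamma MLE
#' first-moment identity).
#'
#' Under the bursty-limit two-state model the fitted shape estimates the
#' burst frequency per mRNA lifetime (`k_on / k_deg`) and the fitted
#' scale the mean transcriptional burst size (`k_tx / k_off`).
#'
#' Integer counts sit awkwardly between the discrete data and the
#' continuous Gamma law: excluding the zero class truncates the
#' small-count mass and biases the fitted scale downward, noticeably so
#' for small burst sizes. The `continuity` option fits on `count + 0.5`
#' (each integer count represented by the midpoint of its unit interval),
#' and `include_zero` then allows the zero class to enter the fit at half
#' a count, which removes most of the truncation bias when estimating
#' burst parameters from simulated telegraph-model counts.
#'
#' @param counts Numeric vector of per-cell counts.
#' @param on_threshold Only counts strictly above this value are fitted
#'   (default 0: all expressing cells).
#' @param continuity If `TRUE`, fit on `count + 0.5`.
#' @param include_zero If `TRUE` (requires `continuity = TRUE` and
#'   `on_threshold = 0`), zero counts are retained and enter the fit as
#'   half a count.
#' @return Object of class `gamma_fit`: `shape`, `scale`, `n_fit`,
#'   `loglik`, `on_threshold`.
#' @export
fit_gamma <- function(counts, on_threshold = 0, continuity = FALSE,
                      include_zero = FALSE) {
  check_number(on_threshold, "on_threshold", lower = 0)
  if (include_zero && !(continuity && on_threshold == 0))
    stopf("'include_zero' requires continuity = TRUE and on_threshold = 0")
  x <- if (include_zero) {
    counts[!is.na(counts)]
  } else {
    counts[!is.na(counts) & counts > on_threshold]
  }
  if (continuity) x <- x + 0.5
  if (length(x) < 20)
    stopf("need >= 20 counts above the ON threshold, got %d", length(x))
  if (var(x) == 0) stopf("counts above the threshold are all equal")
  mx <- mean(x)
  s <- log(mx) - mean(log(x))
  if (!is.finite(s) || s <= 0)
    stopf("degenerate sample: cannot fit a Gamma distribution")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (iter in 1:200) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    while (a_new <= 0) {
      step <- step / 2
      a_new <- a - step
    }
    if (abs(a_new - a) < 1e-12 * a) {
      a <- a_new
      break
    }
    a <- a_new
  }
  b <- mx / a
  structure(
    list(shape = a, scale = b, n_fit = length(x),
         loglik = sum(dgamma(x, shape = a, scale = b, log = TRUE)),
         on_threshold = on_threshold),
    class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma fit (n = %d above threshold %g):\n", x$n_fit, x$on_threshold))
  cat(sprintf(
    "  shape %.4g (burst frequency / mRNA lifetime)\n  scale %.4g (mean burst size)\n",
    x$shape, x$scale))
  cat(sprintf("  log-likelihood %.2f\n", x$loglik))
  invisible(x)
}

#' Mean transcriptional burst size of a fitted Gamma
#'
#' In the bursty limit the Gamma scale parameter is the mean number of
#' transcripts produced per promoter ON episode.
#'
#' @param fit A `gamma_fit` from [fit_gamma()].
#' @return The fitted scale.
#' @export
burst_size <- function(fit) {
  stopifnot(inherits(fit, "gamma_fit"))
  fit$scale
}
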