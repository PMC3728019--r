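# internal argument checks and seeded evaluation

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stopf("'%s' must be a single number", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower) {
    if (x <= lower) stopf("'%s' must be > %s", name, lower)
  } else if (x < lower) {
    stopf("'%s' must be >= %s", name, lower)
  }
  if (x > upper) stopf("'%s' must be <= %s", name, upper)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("'%s' must be an integer", name)
  invisible(as.integer(x))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; with a NULL seed the expression runs on the current stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
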