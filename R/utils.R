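# Internal helpers: seed streams, checks, small numerics.

# Derive a child seed from a master seed and an integer stream id.
# Keeps results reproducible while giving each pipeline stage / replicate an
# independent stream; stays below 2^31 - 1.
derive_seed <- function(master, stream) {
  # products stay below 2^53, so double arithmetic is exact here
  as.integer((as.numeric(master) * 48271 +
                as.numeric(stream) * 10007) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, lo = 0, hi = 1,
                       lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_param(sprintf("`%s` must be a single number in %s%g, %g%s, got %s",
                       name, if (lo_open) "(" else "[", lo, hi,
                       if (hi_open) ")" else "]",
                       paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == round(x)
  if (!ok) stop_param(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

# Standardize a vector; degenerate (zero-variance) input is an error unless
# the caller opts out, because every downstream design works on z-scores.
zscale <- function(x, what = "score") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_param(sprintf("degenerate %s: zero variance, cannot standardize",
                       what))
  }
  (x - mean(x)) / s
}

# Fisher-z confidence interval for a correlation.
fisher_ci <- function(r, n, level = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}
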