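# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_invalid("`%s` must be a finite number in [%s, %s]", name, lo, hi)
  invisible(x)
}

# centred moving average; width in samples (forced odd), edges use shrinking windows
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# deterministic sub-seed derivation; keeps values under 2^31 - 1
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(counter)) %% 2147483647)
}

# two-sided rank test with the package's zero-variance convention (p = 1)
rank_test_p <- function(x, y = NULL, paired = FALSE) {
  if (paired) {
    d <- x - y
    d <- d[is.finite(d)]
    if (length(d) == 0L || all(d == 0)) return(1)
    p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) == 0L || length(y) == 0L) return(1)
    if (length(unique(c(x, y))) == 1L) return(1)
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  if (!is.finite(p)) 1 else p
}

# significance stars at the 0.05 / 0.01 / 0.001 / 0.0001 thresholds
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s."), right = FALSE)
}
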