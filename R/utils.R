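# Internal helpers shared across modules.

# Derive a per-stage RNG seed from a user seed. Offsets keep independent
# stages on distinct, reproducible streams; modulus keeps the result a
# valid 32-bit integer seed.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647L)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.assertPositive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stop(sprintf("'%s' must be a single %s number", name,
                        if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}

# log(sum(exp(x))) without overflow; used by the log-space hypergeometric tail.
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.upperQuartile <- function(x) stats::quantile(x, 0.75, names = FALSE, type = 7)
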