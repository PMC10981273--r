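# Internal helpers shared across modules.

Z95 <- stats::qnorm(0.975)

# Two-sided normal p-value from an estimate and its standard error.
# se == 0 collapses to a point mass: p = 0 unless the estimate is 0.
z_pval <- function(beta, se) {
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(beta) / se), ifelse(beta == 0, 1, 0))
  # guard against underflow to an exact 0 (p-values live in (0, 1])
  p <- ifelse(se > 0 & p == 0, .Machine$double.xmin, p)
  as.numeric(p)
}

# Derive a reproducible sub-seed from a base seed and a stream index.
# Lehmer-style mixing keeps the result a valid 32-bit R seed; base*48271+k
# stays well below 2^53 so the double arithmetic is exact.
split_seed <- function(seed, stream) {
  as.integer((abs(seed) * 48271 + stream * 2654435769) %% 2147483647L)
}

# Run code under a local RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)
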