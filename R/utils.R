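#' @keywords internal
"_PACKAGE"

# Largest-remainder (Hamilton) apportionment of `n` items by `weights`.
# Deterministic: floor quotas first, then remainders in decreasing fractional
# order, ties broken by index. Returns integer counts summing exactly to n.
largest_remainder <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  q <- n * weights / sum(weights)
  counts <- floor(q)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- q - counts
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a master seed; stays inside 32-bit
# integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

stop_flowmrd <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
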