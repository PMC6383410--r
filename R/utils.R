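# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb the global stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stage-specific sub-seed from a master seed; kept in [1, 2^31 - 2]
# so it is always a valid 32-bit integer seed.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %% 2147483646 + 1)
}

# Half-up rounding for report-time percentages; full precision is kept
# internally everywhere.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
    stop(sprintf("'%s' must be a single nonnegative integer", name), call. = FALSE)
  as.integer(x)
}

isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
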