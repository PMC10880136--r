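# Internal helpers: seeded evaluation and deterministic seed fan-out.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's RNG
# state is untouched. All randomness in the package funnels through this.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stage-specific seed from a run seed and a stage tag, so pipeline
# stages can be re-run in isolation. Plain polynomial string hash, kept below
# 2^31 so the result is a valid R integer seed.
stageSeed <- function(seed, tag) {
  stopifnot(is.character(tag), length(tag) == 1L)
  m <- 2147483629
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 131 + cc) %% m
  as.integer((as.numeric(seed) %% m * 7919 + h) %% m)
}

# Integer cell key for (col, row) pairs, unique for |col|,|row| < 2^25.
cellKey <- function(col, row) col * 67108864 + row

`%||%` <- function(a, b) if (is.null(a)) b else a
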