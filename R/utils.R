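# Seed plumbing: every random draw in the package flows from one user seed
# through named substreams, so stages rerun identically in isolation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a 32-bit-safe stage seed from a base seed and a stream id.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
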