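# Deterministic sub-seed streams. Every function that consumes randomness
# takes one integer seed and derives the seeds of its internal stages with
# this map, so a single master seed fixes the whole pipeline. The multiplier
# and increment are primes; results stay inside the 32-bit integer range
# (exact in double arithmetic: the intermediate is < 2^53).
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1299721) %% 2147483629)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# canonical "i-j" (i < j) keys for undirected edges, used wherever edge
# sets are compared
edge_keys <- function(i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  paste0(lo, "-", hi)
}
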