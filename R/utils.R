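# round-half-up to `digits` decimals; published boundary tables use this
# convention rather than IEEE round-half-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-12) / p
}

# Run `fn(rep)` for rep = 1..n_reps, each on its own L'Ecuyer-CMRG RNG
# substream spawned from `seed`, so results do not depend on execution order.
# The caller's RNG state is restored afterwards.
with_substreams <- function(seed, n_reps, fn) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    assign(".Random.seed", stream, globalenv())
    out[[r]] <- fn(r)
    stream <- parallel::nextRNGStream(stream)
  }
  out
}
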