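## Evaluate `expr` under a local RNG state seeded with `seed`.
## Restores the caller's RNG state afterwards, so seeded helpers never
## perturb an enclosing simulation stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Round half away from zero (4-button scale: 2.5 -> 3), unlike base round().
round_half_up <- function(x) floor(x + 0.5)

## Derive a child seed from a parent seed and a stage offset, kept inside
## the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647)
}
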