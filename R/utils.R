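# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package internals never disturb user-level streams.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Number of unordered half-splits of n samples into groups of sizes
# (floor(n/2), ceil(n/2)).
n_half_partitions <- function(n) {
  h <- floor(n / 2)
  if (n %% 2 == 0) choose(n, h) / 2 else choose(n, h)
}
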