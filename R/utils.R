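# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps cohort generation a pure function
# of its seeds without clobbering the user's random stream.
local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic per-case seed derivation; stays below 2^31.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}
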