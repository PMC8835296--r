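# internal helpers

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a stage-specific child seed from a run seed, kept inside 32-bit range
derive_seed <- function(seed, stage) {
  offsets <- c(phantom = 101L, split = 211L, train = 307L, predict = 401L,
               boot = 503L, noise = 601L, cohort = 701L)
  off <- offsets[[stage]]
  ((as.integer(seed) %% 268435L) * 7919L + off) %% 2147483647L
}
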