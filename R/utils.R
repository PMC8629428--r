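## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards. `seed = NULL` evaluates
## without touching the RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

## Derive a distinct 31-bit sub-seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483629
}
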