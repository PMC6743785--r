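# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

# deterministic per-trial seed derivation, kept within 32-bit integer range
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 1009 + 7919 * as.numeric(index)) %% 2147483629)
}

rms <- function(x) sqrt(mean(x^2))
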