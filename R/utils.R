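# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state: all package randomness flows through this
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
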