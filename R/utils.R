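## Run code with a locally seeded RNG, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## derive a sub-seed from a base seed and a tag, staying below 2^31
derive_seed <- function(seed, tag) {
  (as.numeric(seed) * 48271 + as.numeric(tag)) %% 2147483647
}
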