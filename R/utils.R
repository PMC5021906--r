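## RNG hygiene: run `expr` under its own seed, then restore the caller's
## generator state, so internal randomized machinery (restarts, null-
## distribution simulation, calibration draws) never perturbs user-level
## reproducibility.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## deterministic stream of replicate seeds below 2^31
derive_seeds <- function(master_seed, n) {
  with_preserved_seed(as.integer(master_seed),
                      sample.int(.Machine$integer.max, n))
}
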