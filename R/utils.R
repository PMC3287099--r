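## Internal helpers shared across modules.

## Evaluate `code` under a temporary RNG seed, restoring the caller's
## random-number state afterwards so seeded generators do not perturb
## surrounding simulations.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministically derive a stream seed from a master seed and one or
## more labels (module name, tumor index, replicate ...). Kept below 2^31
## so the result is a valid R integer seed.
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(part, "|"))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
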