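# Internal helpers.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-sample seed spawn: n child seeds from one master seed,
# drawn without replacement from the 31-bit integer range.
.spawnSeeds <- function(masterSeed, n) {
  .withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

.isCount <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 &&
  x == round(x)

.isNumber <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
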