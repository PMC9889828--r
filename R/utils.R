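# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic derived seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 33 + as.numeric(offset) * 100003) %% 2147483629L)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

isCount <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}
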