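# internal helpers: deterministic seed derivation and scoped RNG use

# 32-bit-safe multiplicative hash chain; all intermediates stay < 2^53 so
# double arithmetic is exact.  Returns an integer in [1, 2^31 - 2].
hash_seed <- function(...) {
  xs <- c(...)
  m <- 2147483647
  h <- 17
  for (x in xs) {
    x <- as.numeric(x) %% m
    h <- (h * 48271 + x + 1) %% m
  }
  as.integer(h + 1)
}

# evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards
with_seed <- function(seed, expr) {
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
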