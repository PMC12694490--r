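# Internal helpers: seeded RNG scoping and seed fan-out.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  Keeps package randomness from
# perturbing user code and vice versa.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible sub-seed for a named pipeline stage from one global
# seed, so stages can be re-run in isolation.  Stays below 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 1000003
  as.integer((as.numeric(seed) %% 1000003) * 1009 + h) %% 2147483587L
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pbip <- function(...) stop(..., call. = FALSE)
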