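# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. All stochastic entry points go through this so a
# single integer seed fully determines their output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split a sequence string into a character vector of single bases.
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

str_from <- function(v) paste0(v, collapse = "")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Maximal runs of TRUE in a logical vector, as a data.frame(start, end),
# 1-based inclusive.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
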