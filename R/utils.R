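## Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Average ranks ascending: smallest value -> rank 1; ties get the mean rank.
rank_ascending <- function(x) {
  r <- rank(x, ties.method = "average")
  names(r) <- names(x)
  r
}

geometric_mean <- function(x) exp(mean(log(x)))

# stats::sd with the n-1 denominator, erroring on length-1 input by design of
# the callers (stability statistics need >= 2 observations).
sample_sd <- function(x) {
  if (length(x) < 2L) stop("sample SD requires at least two observations")
  stats::sd(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
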