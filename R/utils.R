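# Internal helpers: deterministic seeding and local RNG scope.

# Derive a reproducible child seed from a pipeline seed and a stage label.
# Keeps results invariant to the order in which stages consume randomness.
stage_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 100000L
  (as.integer(seed) %% 21474L) * 100000L + h
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
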