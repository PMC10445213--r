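# Internal helpers shared across modules.

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a base seed and integer tags.
# Kept inside .Machine$integer.max.
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  tags <- c(...)
  s <- as.double(seed)
  for (tag in tags) s <- (s * 69069 + as.double(tag)) %% 2147483629
  as.integer(s)
}

# Gamma draw parameterized by mean and shape (shape fixed, scale = mean/shape).
rgamma_mean <- function(n, mean, shape) {
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
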