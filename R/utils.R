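`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream; a NULL seed leaves the stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_whole <- function(x, tol = 1e-8) all(abs(x - round(x)) <= tol)

upper_vec <- function(m) m[upper.tri(m)]
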