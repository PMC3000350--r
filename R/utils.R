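# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clip01 <- function(v) pmin(1, pmax(0, v))

# 0/1 integer vector coercion with validation; accepts binned_train,
# integer/numeric/logical vectors.
as_binary_vector <- function(x, arg = deparse(substitute(x))) {
  v <- as.integer(unclass(x))
  if (length(v) < 1L) stop(sprintf("`%s` must have at least one bin", arg), call. = FALSE)
  if (anyNA(v) || !all(v == 0L | v == 1L)) {
    stop(sprintf("`%s` must contain only 0/1 values (binarize first: one spike per bin at most)", arg),
         call. = FALSE)
  }
  v
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && abs(x - round(x)) < tol
}
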