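# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched, so all randomness is controlled by explicit seeds
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a base seed; kept strictly below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p)) %% 2147483629
  as.integer(s + 1)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_numeric_matrix <- function(X, what = "X") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop_input("%s must be a numeric matrix", what)
  if (anyNA(X)) stop_input("%s contains missing values", what)
  X
}
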