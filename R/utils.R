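# Internal helpers shared across modules.

#' @importFrom stats rnorm runif pt qt sd var median quantile t.test coef predict residuals fitted
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All exported functions that consume randomness route through this so that a
# `seed` argument never clobbers the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Derive a child seed from (seed, index) that stays inside 32-bit integer range
# and is deterministic and order-independent. Linear congruential mix.
child_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + as.numeric(index) * 69621) %% m)
}

deg2rad <- function(deg) deg * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what), call. = FALSE)
}
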