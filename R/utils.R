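# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and small integer tags, staying
# well inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) s <- (s * 69069 + as.double(t) + 1) %% 2147483647
  as.integer(s)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be finite and > 0", what), call. = FALSE)
  invisible(x)
}

# Log floor applied to per-pixel log densities (near the double underflow
# boundary) so that empty-density pixels never contribute -Inf.
LOG_DENSITY_FLOOR <- -745

# Floor for Monte-Carlo estimates of the bounded-support normalizer.
NORMALIZER_FLOOR <- 1e-12

bgg_verbose <- function() isTRUE(getOption("bggreg.verbose", FALSE))

bgg_log <- function(fmt, ...) {
  if (bgg_verbose()) message(sprintf(fmt, ...))
}
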