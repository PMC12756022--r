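#' @keywords internal
"_PACKAGE"

# Shared small helpers: seeded RNG scoping, seed derivation, validation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a master seed and a string tag.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, tag, index = 0L) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  val <- (as.double(seed) * 48271 + h * 16807 + as.double(index) * 69621) %% 2147483647
  as.integer(val)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 &&
  x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numerically safe sigmoid / softmax / log helpers used across modules.
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise softmax of a matrix.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Exact GELU, x * Phi(x), and its derivative.
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
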