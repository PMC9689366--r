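# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a bounded sub-seed from a global seed and a stream label, so that
# independent pipeline stages (simulate / init / train / mc) consume
# independent but reproducible streams.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

assert_patch <- function(x, what = "patch", size = 32L) {
  if (!is.matrix(x) || nrow(x) != size || ncol(x) != size) {
    stopf("%s must be a %dx%d matrix, got %s", what, size, size,
          paste(dim(x), collapse = "x"))
  }
  invisible(x)
}
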