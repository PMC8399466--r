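#' @keywords internal
"_PACKAGE"

# Run an expression with a locally seeded RNG, restoring global state after.
# All stochastic entry points route through this so results are pure
# functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
    invisible(stats::runif(8))   # decorrelate streams from nearby seeds
  }
  expr
}

# Derive a deterministic child seed from a master seed and a stream label,
# keeping the result inside the 32-bit integer range. The label hash is put
# through two multiplicative scrambling rounds so that labels differing in a
# single character yield well-separated seeds (the first draws after
# set.seed() are visibly correlated across near-consecutive seeds).
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  ch <- utf8ToInt(as.character(stream))
  h <- as.numeric(seed)
  for (c in ch) h <- (h * 31 + c) %% 2147483647
  h <- (h * 48271) %% 2147483647      # Lehmer steps to scramble
  h <- (h * 48271) %% 2147483647
  as.integer(h)
}

stop_named <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(code, "gazebias_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
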