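#' @useDynLib ymazer, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Deterministic substream derivation from a master seed. Knuth-style
# multiplicative hash, folded into [0, 2^31 - 1]. Stream keys are small
# integers or short strings (hashed to an integer first).
derive_seed <- function(master, key) {
  if (is.character(key)) {
    key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131)
  }
  x <- (as.double(master) * 2654435761 + as.double(key) * 40503 + 97) %% 2147483647
  as.integer(max(1, x))
}

# Polynomial rolling hash (mod 2^31 - 1, exact in double arithmetic) over a
# character scalar; returns an 8-hex-digit string. Used for config and report
# hashing so that runs are comparable without external digest dependencies.
# Two passes with different multipliers are concatenated to tame collisions.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.double(charToRaw(x))
  m <- 2147483647
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% m
    h2 <- (h2 * 131 + b) %% m
  }
  paste0(sprintf("%08x", as.integer(h1)), sprintf("%08x", as.integer(h2)))
}

# Stable JSON serialization of a (possibly nested) R object for hashing.
stable_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12,
                                null = "null", force = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
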