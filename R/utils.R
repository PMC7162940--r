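# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing so that independent stages / participants get
#' reproducible but distinct RNG streams. Stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index integer stream index (>= 0).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(master, index) {
  master <- as.integer(master) %% 2147483647L
  # two rounds of a multiplicative hash, all in double precision but exactly
  # representable (< 2^53) before the final modulus
  h <- (as.double(master) * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  h <- (h * 69621) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  expr
}

# Row-wise log(sum(exp(.))) for a matrix of log terms.
row_logsumexp <- function(lm) {
  m <- apply(lm, 1L, max)
  m + log(rowSums(exp(lm - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
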