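#' @keywords internal
"_PACKAGE"

# Modulus for all derived seeds; largest prime < 2^31 keeps seeds valid
# 32-bit integers for set.seed().
.SEED_MOD <- 2147483629

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that take a `seed`
#' argument never disturb the caller's RNG stream.
#' @noRd
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
    set.seed(as.integer(seed %% .SEED_MOD))
  }
  force(expr)
}

#' Deterministic sub-seed for a labelled unit of work
#'
#' Hashes a character label (e.g. a probe identifier) into the seed space and
#' offsets it by the master seed, so per-probe randomness depends on the probe
#' identity, not its position in the matrix.
#' @noRd
derive_seed <- function(master_seed, label) {
  h <- 0
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% .SEED_MOD
  }
  as.integer((as.numeric(master_seed) + h) %% .SEED_MOD)
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
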