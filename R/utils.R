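# Internal helpers shared across modules.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Wrap angles in degrees onto (-180, 180]
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @keywords internal
#' @noRd
wrap_deg <- function(a) {
  r <- a %% 360
  r[r > 180] <- r[r > 180] - 360
  r
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic counter scheme: each (stream, index) pair maps to a fixed
#' 31-bit integer, so per-observation simulations are independent of the
#' order in which they are produced.  Knuth-style multiplicative mixing,
#' kept inside 2^31 - 1 via double arithmetic (exact below 2^53).
#'
#' @param master_seed integer master seed.
#' @param stream integer stream id (e.g. species index).
#' @param index integer counter within the stream.
#' @return a single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, stream = 0L, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- (as.numeric(master_seed) %% m)
  h <- (h * 48271 + as.numeric(stream) * 69621 + 1) %% m
  h <- (h * 48271 + as.numeric(index) * 16807 + 1) %% m
  as.integer(h %% (m - 1L) + 1)
}

# Evaluate `expr` with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
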