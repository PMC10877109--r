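#' Round half away from zero
#'
#' Integer rounding with ties going up (7/9 of 100 -> 78, 13/15 of 100 -> 87),
#' unlike [base::round()]'s banker's rounding. Used for every printed
#' percentage so reported tables are reproducible digit for digit.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 7 / 9)   # 78
#' round_half_up(100 * 13 / 15) # 87
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Run code under a temporary, restorable RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label; keeps all
# per-slide / per-module randomness reproducible from one user seed while
# staying inside 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}
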