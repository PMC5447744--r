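#' Evaluate code with a local, restored RNG state
#'
#' All stochastic operations in the package funnel their randomness through
#' this helper so that every function taking a `seed` argument is reproducible
#' and leaves the caller's RNG stream untouched.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Uses a fixed affine congruential map so per-subject / per-stage substreams
#' are decoupled but fully determined by the master seed. The result stays
#' inside the 32-bit signed integer range.
#'
#' @param seed Master seed (integer scalar).
#' @param offset Integer stream offset (small non-negative integer).
#' @return Integer seed in `[1, 2147483629]`.
#' @keywords internal
derive_seed <- function(seed, offset) {
  # doubles stay exact here: |seed| < 2^31 so seed*48271 + offset*2654435761 < 2^53
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 2654435761) %% 2147483629
  as.integer(s) + 1L
}

# argument validation helpers ------------------------------------------------

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop(sprintf("`%s` must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  as.integer(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Collapse runs of whitespace in marker codes
#'
#' BrainVision writers differ in how they pad stimulus codes ("S 2" vs
#' "S  2"); codes are compared after collapsing internal whitespace runs to a
#' single space and trimming.
#' @keywords internal
normalize_code <- function(x) {
  gsub("\\s+", " ", trimws(x))
}
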