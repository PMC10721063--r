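#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves going up (away from
#' zero), the convention used by the bundled reference tables; `base::round()`
#' rounds halves to even, which does not reproduce them (e.g. a specificity of
#' 99.77 prints as 100).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(0.5, 1.5, 92.888), 0)
#' round_half_up(91.093, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a child seed from a global seed and a stage offset, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483647)
}

# Seed-scoped evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}
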