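#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero on the
#' positive axis (so 0.05 -> 0.1), unlike [base::round()]'s round-half-even.
#' All cohort percentages reported by this package use this convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(80.4926, 1)  # 80.5
#' round_half_up(0.05, 1)     # 0.1
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Percentage with round-half-up to one decimal
#'
#' @param num numerator count.
#' @param den denominator count; a zero denominator yields 0 (an empty
#'   stratum is reported as a zero rate, not an error).
#' @return percent on the 0-100 scale, one decimal.
#' @export
pct <- function(num, den) {
  if (length(den) == 1L && den == 0) return(0)
  round_half_up(100 * num / den, 1)
}

# Run code under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Derive a per-stage sub-seed from the master seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}
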