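#' @importFrom rlang %||% hash
#' @importFrom stats cor median quantile rbinom runif setNames
#' @importFrom utils combn read.delim write.table
NULL

# round() in R rounds half to even; tabulated percentages here use
# conventional half-up rounding so 37.25 -> 37.3, not 37.2.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

assert_probability <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be numeric in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) ||
      any(x != floor(x)) || any(x < min)) {
    stop(sprintf("%s must be integer(s) >= %d", what, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Derive a reproducible sub-seed so every generator stage draws from an
# independent, fixed stream under one top-level seed.  Kept < 2^31 - 1.
sub_seed <- function(seed, offset) {
  (as.double(seed) * 1103L + as.double(offset)) %% 2147483629
}
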