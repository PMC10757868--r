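#' @importFrom rlang abort warn .data %||%
#' @importFrom stats median pchisq pnorm qchisq qnorm quantile rbinom rexp
#'   runif setNames stepfun uniroot integrate dnorm var sd
NULL

# round-half-up (base round() is round-half-even); used for printed-style
# integer percentages
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

pct_of <- function(num, denom) round_half_up(100 * num / denom)

# run `expr` under a local RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_number(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
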