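# Internal helpers: bit twiddling, exact powers of two, hashing.

# Number of set bits for each value in x (non-negative integers < 2^31).
popcount <- function(x) {
  n <- integer(length(x))
  x <- as.integer(x)
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Exact power of two as a decimal string
#'
#' Computes 2^n in exact integer arithmetic (schoolbook doubling on a digit
#' vector), so counts such as 2^116 are reported without floating-point loss.
#'
#' @param n Non-negative integer exponent.
#' @return A character scalar holding the exact decimal expansion of 2^n.
#' @examples
#' pow2_decimal(10)   # "1024"
#' pow2_decimal(116)
#' @export
pow2_decimal <- function(n) {
  stopifnot(length(n) == 1L, n >= 0, n == floor(n))
  digits <- 1L  # little-endian base-10 digits
  for (i in seq_len(n)) {
    digits <- digits * 2L
    carry <- 0L
    for (k in seq_along(digits)) {
      d <- digits[k] + carry
      digits[k] <- d %% 10L
      carry <- d %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(digits), collapse = "")
}

# log10 of 2^n, exact enough for order-of-magnitude arithmetic.
log10_pow2 <- function(n) n * log10(2)

# Format a count given its log10 as "a.b x 10^k" at `sig` significant figures.
sci_from_log10 <- function(lg, sig = 2L) {
  k <- floor(lg)
  mant <- round(10^(lg - k), sig - 1L)
  if (mant >= 10) {  # rounding pushed the mantissa over a decade
    mant <- mant / 10
    k <- k + 1
  }
  sprintf("%.*fx10^%d", sig - 1L, mant, k)
}

# Round half away from zero (ages at .5 go to the farther integer).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# MD5 of a canonical string, via a temporary file (base R has no string md5).
md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
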