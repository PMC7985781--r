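#' Exact rational numbers for series coefficients
#'
#' A minimal exact-rational scalar type used wherever the uniform-lag
#' expansion coefficients must be carried without floating-point error.
#' Numerator and denominator are kept as exactly represented integers
#' (magnitude below 2^53) and reduced by their greatest common divisor after
#' every operation; an overflow past exact-integer range raises an error
#' rather than silently losing precision.
#'
#' @param num integer numerator.
#' @param den integer denominator (nonzero).
#' @return An object of class `uxp_rational`.
#' @examples
#' rational(8, 3)
#' as.numeric(rational(8, 3))
#' @export
rational <- function(num, den = 1) {
  if (!is.numeric(num) || !is.numeric(den) || length(num) != 1L || length(den) != 1L ||
      num != round(num) || den != round(den)) {
    abort_argument("`num` and `den` must be single integers.")
  }
  if (den == 0) abort_argument("rational denominator must be nonzero.")
  q_new(num, den)
}

MAX_EXACT_INT <- 2^53

q_new <- function(num, den) {
  if (abs(num) >= MAX_EXACT_INT || abs(den) >= MAX_EXACT_INT) {
    abort_internal("rational arithmetic overflow beyond exact integer range.")
  }
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- q_gcd(abs(num), den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  structure(list(num = num, den = den), class = "uxp_rational")
}

q_gcd <- function(a, b) {
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  max(a, 1)
}

q_add <- function(x, y) {
  # reduce before multiplying to keep intermediates small
  g <- q_gcd(x$den, y$den)
  dx <- x$den / g
  dy <- y$den / g
  q_new(x$num * dy + y$num * dx, dx * y$den)
}

q_mul <- function(x, y) {
  g1 <- q_gcd(abs(x$num), y$den)
  g2 <- q_gcd(abs(y$num), x$den)
  q_new((x$num / g1) * (y$num / g2), (x$den / g2) * (y$den / g1))
}

q_neg <- function(x) q_new(-x$num, x$den)

# x^e / e! for integer base x and integer exponent e >= 0, exactly
q_pow_over_fact <- function(x, e) {
  num <- 1
  den <- 1
  for (i in seq_len(e)) {
    num <- num * x
    den <- den * i
    if (abs(num) >= MAX_EXACT_INT || den >= MAX_EXACT_INT) {
      abort_internal("rational arithmetic overflow beyond exact integer range.")
    }
  }
  q_new(num, den)
}

q_equal <- function(x, y) x$num == y$num && x$den == y$den

q_zero <- function() q_new(0, 1)
q_one <- function() q_new(1, 1)

q_dbl <- function(x) x$num / x$den

#' @export
as.double.uxp_rational <- function(x, ...) x$num / x$den

#' @export
as.character.uxp_rational <- function(x, ...) {
  if (x$den == 1) sprintf("%.0f", x$num) else sprintf("%.0f/%.0f", x$num, x$den)
}

#' @export
format.uxp_rational <- function(x, ...) as.character(x)

#' @export
print.uxp_rational <- function(x, ...) {
  cat("<rational> ", as.character(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.uxp_rational` <- function(e1, e2) {
  if (!inherits(e2, "uxp_rational")) e2 <- rational(e2)
  if (!inherits(e1, "uxp_rational")) e1 <- rational(e1)
  q_equal(e1, e2)
}
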