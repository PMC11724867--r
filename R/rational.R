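#' Exact rational numbers for count statistics
#'
#' Per-gene means and Fano factors of integer count data are ratios of
#' integers (mean = T/n_c, FF = (n_c*S - T^2)/(n_c*T) with T = sum of
#' counts, S = sum of squared counts). The quantization statements this
#' package makes -- means sit exactly on i/n_c, vertical spacings are
#' exact integer multiples of 1/n_c -- only hold in exact arithmetic, so
#' all curve, lattice and spacing logic runs on this rational vector
#' class and converts to double only at presentation boundaries.
#'
#' Numerators and denominators are stored as integer-valued doubles and
#' kept reduced (GCD 1, denominator positive). Operations abort if an
#' intermediate product would leave the exactly-representable integer
#' range of a double (|x| < 2^53), rather than silently losing precision.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (non-zero); recycled.
#' @return A `rational` vector.
#' @examples
#' rational(1, 3) + rational(1, 6)   # 1/2
#' rational(7, 101) == rational(14, 202)
#' as.numeric(rational(2, 8))
#' @export
rational <- function(num, den = 1) {
  if (!is.numeric(num) || !is.numeric(den)) {
    stop("rational() needs numeric (integer-valued) inputs", call. = FALSE)
  }
  num <- as.double(num)
  den <- as.double(den)
  if (any(num != round(num)) || any(den != round(den))) {
    stop("rational() components must be integer-valued", call. = FALSE)
  }
  if (any(den == 0)) stop("rational() denominator must be non-zero", call. = FALSE)
  n <- max(length(num), length(den))
  new_rational(rep_len(num, n), rep_len(den, n))
}

# internal constructor: reduces and normalizes sign
new_rational <- function(num, den) {
  .rat_guard(num)
  .rat_guard(den)
  s <- ifelse(den < 0, -1, 1)
  num <- num * s
  den <- den * s
  g <- .gcd2(num, den)
  structure(list(num = num / g, den = den / g), class = "rational")
}

# gcd of |a| and |b|, elementwise Euclid on integer-valued doubles;
# finished elements (b == 0) are left untouched while others iterate
.gcd <- function(a, b) {
  repeat {
    idx <- which(b != 0)
    if (!length(idx)) return(a)
    r <- a[idx] %% b[idx]
    a[idx] <- b[idx]
    b[idx] <- r
  }
}

.gcd2 <- function(num, den) {
  g <- .gcd(abs(num), abs(den))
  g[g == 0] <- 1
  g
}

.rat_guard <- function(x) {
  if (any(abs(x) >= 2^53)) {
    stop("exact rational arithmetic overflow (|integer| >= 2^53)", call. = FALSE)
  }
  invisible(x)
}

as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (!is.numeric(x) || any(x != round(x))) {
    stop("cannot coerce non-integer numeric to rational exactly", call. = FALSE)
  }
  rational(x, 1)
}

#' @rdname rational
#' @param x object to test or convert.
#' @export
is_rational <- function(x) inherits(x, "rational")

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) new_rational(x$num[i], x$den[i])

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), as_rational)
  new_rational(unlist(lapply(parts, `[[`, "num")),
               unlist(lapply(parts, `[[`, "den")))
}

#' @export
as.numeric.rational <- function(x, ...) x$num / x$den

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat("<rational[", length(x), "]> ", paste(format(x), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Numerator and denominator of a rational vector
#'
#' Values are returned in fully reduced form (denominator positive).
#'
#' @param x a [rational()] vector.
#' @return integer-valued double vector.
#' @export
rat_num <- function(x) as_rational(x)$num

#' @rdname rat_num
#' @export
rat_den <- function(x) as_rational(x)$den

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    e1 <- as_rational(e1)
    return(switch(.Generic,
      "+" = e1,
      "-" = new_rational(-e1$num, e1$den),
      stop("unary ", .Generic, " not defined for rational", call. = FALSE)
    ))
  }
  e1 <- as_rational(e1)
  e2 <- as_rational(e2)
  n <- max(length(e1$num), length(e2$num))
  a <- rep_len(e1$num, n); b <- rep_len(e1$den, n)
  c <- rep_len(e2$num, n); d <- rep_len(e2$den, n)
  switch(.Generic,
    "+" = new_rational(a * d + c * b, b * d),
    "-" = new_rational(a * d - c * b, b * d),
    "*" = new_rational(a * c, b * d),
    "/" = {
      if (any(c == 0)) stop("rational division by zero", call. = FALSE)
      new_rational(a * d, b * c)
    },
    "==" = { .rat_guard(a * d); .rat_guard(c * b); a * d == c * b },
    "!=" = a * d != c * b,
    "<"  = a * d <  c * b,
    "<=" = a * d <= c * b,
    ">"  = a * d >  c * b,
    ">=" = a * d >= c * b,
    stop(.Generic, " not defined for rational", call. = FALSE)
  )
}

# elementwise max(x, y) for rationals (used for the lower bound clamp)
rat_pmax <- function(x, y) {
  x <- as_rational(x)
  y <- as_rational(y)
  n <- max(length(x), length(y))
  xi <- rep_len(seq_along(x$num), n)
  yi <- rep_len(seq_along(y$num), n)
  take_y <- (x$num[xi] * y$den[yi]) < (y$num[yi] * x$den[xi])
  new_rational(ifelse(take_y, y$num[yi], x$num[xi]),
               ifelse(take_y, y$den[yi], x$den[xi]))
}
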