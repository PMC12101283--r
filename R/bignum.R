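# Minimal arbitrary-precision non-negative integers, stored as little-endian
# digit vectors in base 1e4. Only what exact library-diversity arithmetic
# needs: multiplication, integer power, decimal formatting.

BIG_BASE <- 10000L

big_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  digits <- integer(0)
  x <- as.numeric(x)
  if (x == 0) digits <- 0L
  while (x > 0) {
    digits <- c(digits, as.integer(x %% BIG_BASE))
    x <- floor(x / BIG_BASE)
  }
  structure(list(digits = digits), class = "bigint")
}

big_mul <- function(a, b) {
  da <- a$digits; db <- b$digits
  res <- numeric(length(da) + length(db))
  for (i in seq_along(da)) {
    res[i:(i + length(db) - 1L)] <- res[i:(i + length(db) - 1L)] + da[i] * db
  }
  # carry propagation (products fit in doubles: < 1e8 per cell times short vectors)
  carry <- 0
  for (i in seq_along(res)) {
    v <- res[i] + carry
    res[i] <- v %% BIG_BASE
    carry <- floor(v / BIG_BASE)
  }
  while (carry > 0) {
    res <- c(res, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  while (length(res) > 1L && res[length(res)] == 0) res <- res[-length(res)]
  structure(list(digits = as.integer(res)), class = "bigint")
}

big_pow <- function(base, exponent) {
  stopifnot(exponent >= 0, exponent == floor(exponent))
  result <- big_from_int(1)
  acc <- big_from_int(base)
  e <- as.integer(exponent)
  while (e > 0L) {
    if (e %% 2L == 1L) result <- big_mul(result, acc)
    e <- e %/% 2L
    if (e > 0L) acc <- big_mul(acc, acc)
  }
  result
}

#' @export
format.bigint <- function(x, ...) {
  d <- rev(x$digits)
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.numeric.bigint <- function(x, ...) {
  sum(x$digits * BIG_BASE^(seq_along(x$digits) - 1))
}
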