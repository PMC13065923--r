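## Minimal exact decimal arithmetic for combinatorial space counting.
## Counts routinely exceed 2^63 (hundred-billion-scale libraries and beyond),
## and no arbitrary-precision package is part of this stack, so totals are
## carried as decimal digit strings with schoolbook add/multiply.

.bigNorm <- function(d) {
  ## d: integer vector of digits, least-significant first, may hold carries
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= 10L) {
      carry <- d[i] %/% 10L
      d[i] <- d[i] %% 10L
      if (i == length(d)) d <- c(d, 0L)
      d[i + 1L] <- d[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0L) d <- d[-length(d)]
  d
}

.bigFromString <- function(s) {
  stopifnot(grepl("^[0-9]+$", s))
  rev(as.integer(strsplit(s, "")[[1]]))
}

.bigToString <- function(d) paste(rev(d), collapse = "")

.bigFromNumeric <- function(x) {
  stopifnot(is.finite(x), x >= 0, x == floor(x), x < 2^53)
  .bigFromString(sprintf("%.0f", x))
}

.bigAdd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, integer(n - length(a)))
  b <- c(b, integer(n - length(b)))
  .bigNorm(a + b)
}

.bigMul <- function(a, b) {
  res <- integer(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0L) next
    res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + a[i] * b
    res <- .bigNorm(c(res, 0L))
    res <- c(res, integer(length(a) + length(b) - length(res)))
  }
  .bigNorm(res)
}

#' Exact product of nonnegative integers as a decimal string
#'
#' @param ... nonnegative integers (as numerics below 2^53 or decimal strings).
#' @return decimal string of the exact product.
#' @export
bigProduct <- function(...) {
  xs <- list(...)
  acc <- .bigFromNumeric(1)
  for (x in xs) {
    d <- if (is.character(x)) .bigFromString(x) else .bigFromNumeric(x)
    acc <- .bigMul(acc, d)
  }
  .bigToString(acc)
}

#' Exact sum of nonnegative integers as a decimal string
#'
#' @param xs vector/list of nonnegative integers or decimal strings.
#' @return decimal string of the exact sum.
#' @export
bigSum <- function(xs) {
  acc <- .bigFromNumeric(0)
  for (x in xs) {
    d <- if (is.character(x)) .bigFromString(x) else .bigFromNumeric(x)
    acc <- .bigAdd(acc, d)
  }
  .bigToString(acc)
}
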