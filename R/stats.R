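## Extrapolation arithmetic for virtual screening: hit-rate estimation with
## Wilson 95% intervals, relative-change computation, and exact count
## aggregation over experiment tables.

#' Virtual-hit-rate estimate with Wilson interval
#'
#' The fraction of a screened random sample that passes all reward
#' components extrapolates the virtual hit rate of the full enumerated
#' library. The point estimate is \code{100 * hits / n} percent; the 95\%
#' confidence interval is the Wilson score interval (via
#' \code{\link[stats]{prop.test}} without continuity correction), which
#' stays well-behaved at small rates.
#'
#' @param hits number of virtual hits in the sample.
#' @param n sample size, > 0.
#' @return a \linkS4class{HitRateResult}; values are unrounded, display
#'   rounding is left to \code{format()}.
#' @export
hitRate <- function(hits, n) {
  if (length(n) != 1 || n <= 0) stop("n must be a single positive count")
  if (hits < 0 || hits > n) stop("hits must lie in [0, n]")
  ci <- stats::prop.test(hits, n, correct = FALSE)$conf.int
  new("HitRateResult", hits = as.numeric(hits), n = as.numeric(n),
      ratePercent = 100 * hits / n, ci95 = 100 * as.numeric(ci))
}

setMethod("show", "HitRateResult", function(object) {
  cat(sprintf("Hit rate: %d/%d = %s%% (95%% CI %s-%s)\n",
              object@hits, object@n,
              formatC(object@ratePercent, digits = 2, format = "f"),
              formatC(object@ci95[1], digits = 2, format = "f"),
              formatC(object@ci95[2], digits = 2, format = "f")))
})

#' Format a hit rate at the table's display precision
#'
#' @param x a \linkS4class{HitRateResult}.
#' @param digits decimal places (screening tables mix 1 and 2 d.p.).
#' @return character scalar like \code{"58.8\%"}.
#' @export
formatHitRate <- function(x, digits = 2) {
  paste0(formatC(x@ratePercent, digits = digits, format = "f"), "%")
}

#' Relative increase of one count over another, in percent
#'
#' @param a new value.
#' @param b reference value, > 0.
#' @return \code{100 * (a - b) / b}.
#' @export
relativeIncrease <- function(a, b) {
  if (b <= 0) stop("reference value must be > 0")
  100 * (a - b) / b
}

#' Aggregate per-experiment counts
#'
#' Exact integer sum of a (experiment, count) table.
#'
#' @param table data.frame with columns \code{experiment_id} and
#'   \code{count}, or a bare numeric vector of counts.
#' @return the total as a numeric (exact; all realistic totals are far
#'   below 2^53).
#' @export
aggregateCounts <- function(table) {
  counts <- if (is.data.frame(table)) table$count else table
  if (!length(counts)) return(0)
  if (any(counts < 0)) stop("counts must be nonnegative")
  sum(as.numeric(counts))
}
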