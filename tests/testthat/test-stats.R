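test_that("hit-rate arithmetic reproduces screening-table values", {
  expect_identical(formatHitRate(hitRate(220466, 375000), 1), "58.8%")
  expect_identical(formatHitRate(hitRate(13090, 50000), 2), "26.18%")
  expect_identical(formatHitRate(hitRate(4457, 50000), 2), "8.91%")
  expect_identical(formatHitRate(hitRate(6821, 50000), 2), "13.64%")
  expect_identical(formatHitRate(hitRate(5119, 50000), 2), "10.24%")
  z <- hitRate(0, 100)
  expect_identical(z@ratePercent, 0)
  expect_equal(z@ci95[1], 0, tolerance = 1e-12)
  expect_error(hitRate(5, 0), "positive")
  expect_error(hitRate(-1, 10))
  expect_error(hitRate(11, 10))
})

test_that("complementary hit rates sum to exactly 100", {
  for (kn in list(c(0, 10), c(3, 7), c(13090, 50000), c(220466, 375000))) {
    k <- kn[1]; n <- kn[2]
    expect_identical(hitRate(k, n)@ratePercent + hitRate(n - k, n)@ratePercent,
                     100)
  }
})

test_that("Wilson interval shrinks with n and attains nominal coverage", {
  # closed-form Wilson oracle, cross-checked against the implementation
  wilson <- function(k, n, z = qnorm(0.975)) {
    p <- k / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)))) /
      (1 + z^2 / n) * 100
  }
  for (kn in list(c(26, 100), c(589, 1000))) {
    expect_equal(hitRate(kn[1], kn[2])@ci95, wilson(kn[1], kn[2]),
                 tolerance = 1e-6)
  }
  widths <- vapply(c(100, 1000, 10000), function(n) {
    ci <- hitRate(round(0.26 * n), n)@ci95
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  set.seed(20260101)
  n <- 400
  for (p in c(0.1, 0.26, 0.59)) {
    k <- rbinom(10000, n, p)
    ci <- vapply(k, wilson, numeric(2), n = n)
    coverage <- mean(ci[1, ] <= 100 * p & 100 * p <= ci[2, ])
    expect_gte(coverage, 0.936)  # nominal 95% less simulation error
  }
})

test_that("relative increase matches direct arithmetic", {
  expect_equal(relativeIncrease(18889, 16686), 13.20268, tolerance = 1e-4)
  expect_identical(round(relativeIncrease(18889, 16686)), 13)
  expect_equal(relativeIncrease(5751, 5419), 6.13, tolerance = 0.005)
  expect_identical(relativeIncrease(42, 42), 0)
  expect_error(relativeIncrease(1, 0), "> 0")
})

test_that("count aggregation is an exact sum", {
  counts <- c(5513, 5751, 5419, 5104, 4523, 3367, 350, 558, 693, 2848)
  expect_identical(aggregateCounts(counts), 34126)
  expect_identical(aggregateCounts(
    data.frame(experiment_id = letters[1:3], count = c(1, 2, 3))), 6)
  expect_identical(aggregateCounts(numeric()), 0)
  expect_identical(aggregateCounts(7), 7)
  expect_error(aggregateCounts(c(1, -2)), "nonnegative")
})
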