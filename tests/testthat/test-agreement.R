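# Concordance and Bland-Altman agreement statistics.

test_that("ccc: perfect concordance, closed-form shift, oracle agreement", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(ccc(x, x), 1)
  # y = x + c: ccc = 2 s^2 / (2 s^2 + c^2) with population moments
  x3 <- c(1, 2, 3)
  expect_equal(ccc(x3, x3 + 1), 4 / 7)
  # direct-formula oracle on a worked pair
  xx <- c(1, 2, 3, 4); yy <- c(1.1, 2.1, 2.9, 4.2)
  n <- 4
  sxy <- sum((xx - mean(xx)) * (yy - mean(yy))) / n
  sx <- sum((xx - mean(xx))^2) / n
  sy <- sum((yy - mean(yy))^2) / n
  ref <- 2 * sxy / (sx + sy + (mean(xx) - mean(yy))^2)
  expect_equal(ccc(xx, yy), ref, tolerance = 1e-12)
})

test_that("ccc contracts: symmetry, shift invariance, bounds, errors", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(ccc(x, y), ccc(y, x), tolerance = 1e-12)
    expect_equal(ccc(x + 5, y + 5), ccc(x, y), tolerance = 1e-9)
    v <- ccc(x, y)
    expect_true(v >= -1 && v <= 1)
    expect_lte(abs(v), abs(cor(x, y)) + 1e-12)
  }
  expect_error(ccc(1:4, 1:5), "equal length")
  expect_error(ccc(c(2, 2, 2), c(2, 2, 2)), "constant")
})

test_that("bland_altman: identity, constant offset, antisymmetry", {
  x <- c(4, 5, 6, 7)
  ba0 <- bland_altman(x, x)
  expect_equal(unlist(ba0), c(bias = 0, loa_low = 0, loa_high = 0))
  ba1 <- bland_altman(x, x - 1)
  expect_equal(unlist(ba1), c(bias = 1, loa_low = 1, loa_high = 1))
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("LoA interval covers ~95% of differences under normal noise", {
  set.seed(1234)
  cover <- replicate(1000, {
    x <- rnorm(20); y <- x + rnorm(20, 0, 0.5)
    ba <- bland_altman(x, y)
    d <- x - y
    mean(d >= ba$loa_low & d <= ba$loa_high)
  })
  expect_gt(mean(cover), 0.90)
})

test_that("agreement_stats combines the pieces coherently", {
  set.seed(8)
  x <- rnorm(15, 50, 3)
  y <- x + rnorm(15, 0, 0.5)
  st <- agreement_stats(x, y)
  expect_equal(st$pearson_r2, cor(x, y)^2)
  expect_lte(st$loa_low, st$bias)
  expect_lte(st$bias, st$loa_high)
  expect_lte(abs(st$ccc), 1)
})
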