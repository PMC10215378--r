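test_that("linlog_eval matches direct substitution and its asymptotes", {
  # c = 0 collapses to the line a + b*x
  expect_equal(linlog_eval(linlog_params(1, 2, 0, 1, 1), 3), 7.0)
  x <- seq(-50, 50, length.out = 101)
  expect_equal(linlog_eval(linlog_params(1.5, 2.25, 0, 1, 1), x),
               1.5 + 2.25 * x)
  # direct substitution at x = 0: e^0 = 1
  p <- ref_params()
  expect_equal(linlog_eval(p, 0), -10 / 101)
  # far above the dip the logistic term saturates at c
  expect_equal(linlog_eval(p, 100), 90, tolerance = 1e-9)
})

test_that("evaluation and slope are overflow-safe at extreme f*x", {
  p <- linlog_params(a = 0, b = 1, c = 10, f = 100, log_d = 0)
  # f*x = +/- 1e4: naive exp(-f*x) would overflow on the negative side
  expect_true(all(is.finite(linlog_eval(p, c(-100, 100)))))
  expect_true(all(is.finite(linlog_slope(p, c(-100, 100)))))
  expect_equal(linlog_eval(p, -100), -100)          # logistic term -> 0
  expect_equal(linlog_eval(p, 100), 100 - 10)       # logistic term -> c
  expect_equal(linlog_slope(p, c(-100, 100)), c(1, 1))
})

test_that("invalid parameters and doses are rejected with named messages", {
  expect_error(linlog_params(0, -1, 1, 1, 1), "`b`")
  expect_error(linlog_params(0, 1, -1, 1, 1), "`c`")
  expect_error(linlog_params(0, 1, 1, 0, 1), "`d`")
  expect_error(linlog_params(0, 1, 1, 1, -2), "`f`")
  expect_error(linlog_params(NA, 1, 1, 1, 1), "`a`")
  expect_error(linlog_eval(ref_params(), c(1, NaN)), "non-finite")
  expect_error(linlog_slope(ref_params(), Inf), "non-finite")
})

test_that("slope matches known values and a finite-difference oracle", {
  # derivative of a line
  expect_equal(linlog_slope(linlog_params(2, 3, 0, 1, 1), c(-4, 0, 9)),
               rep(3, 3))
  # the logistic derivative peaks at c*f/4 at its midpoint log(d)/f
  p <- linlog_params(1, 2, 20, f = 1.5, log_d = 3)
  expect_equal(linlog_slope(p, 3 / 1.5), 2 - 20 * 1.5 / 4)
  # central finite difference of linlog_eval
  p <- ref_params()
  h <- 1e-6
  fd <- (linlog_eval(p, 2 + h) - linlog_eval(p, 2 - h)) / (2 * h)
  expect_equal(linlog_slope(p, 2), fd, tolerance = 1e-6)
})

test_that("closed-form stationary doses match the numeric root oracle", {
  p <- ref_params()
  st <- stationary_points(p)
  expect_identical(st$regime, "two_points")
  oracle <- numeric_stationary(p)
  expect_equal(st$rmax, oracle$rmax, tolerance = 1e-9)
  expect_equal(st$rmin, oracle$rmin, tolerance = 1e-9)
  # frozen values from the root-finding oracle
  expect_equal(st$rmax, 2.5417326, tolerance = 1e-6)
  expect_equal(st$rmin, 6.6686077, tolerance = 1e-6)
  # slope vanishes at both
  expect_equal(linlog_slope(p, c(st$rmax, st$rmin)), c(0, 0),
               tolerance = 1e-12)
})

test_that("discriminant sign determines the regime", {
  # c*f = 2 < 4b = 4: no stationary point
  st <- stationary_points(linlog_params(0, 1, 2, 10, 1))
  expect_identical(st$regime, "monotone")
  expect_true(is.na(st$rmax) && is.na(st$rmin))
  # c*f = 4b exactly: double root at log(d)/f
  st <- stationary_points(linlog_params(0, 1, 4, 50, 1))
  expect_identical(st$regime, "degenerate")
  expect_equal(st$rmax, log(50))
  expect_equal(st$rmin, log(50))
  # c = 0: pure line
  expect_identical(classify_regime(linlog_params(0, 1, 0, 1, 1)), "monotone")
  # projections agree with stationary_points
  expect_identical(classify_regime(ref_params()), "two_points")
  expect_identical(classify_regime(linlog_params(0, 1, 2, 10, 1)), "monotone")
  expect_identical(classify_regime(linlog_params(0, 1, 4, 50, 1)), "degenerate")
})

test_that("stationary-dose geometry holds over random two-point draws", {
  draws <- draw_two_point_params(300, seed = 11)
  for (p in draws) {
    st <- stationary_points(p)
    expect_identical(st$regime, "two_points")
    # ordering and the exact symmetry Rmax + Rmin = 2 log(d)/f
    expect_true(st$rmax < st$rmin)
    expect_equal(st$rmax + st$rmin, 2 * p$log_d / p$f,
                 tolerance = 1e-9)
    # local max above local min; slope negative between, positive outside
    expect_gt(linlog_eval(p, st$rmax), linlog_eval(p, st$rmin))
    mid <- (st$rmax + st$rmin) / 2
    gap <- st$rmin - st$rmax
    expect_lt(linlog_slope(p, mid), 0)
    expect_gt(linlog_slope(p, st$rmax - gap), 0)
    expect_gt(linlog_slope(p, st$rmin + gap), 0)
  }
})

test_that("monotone draws have strictly positive slope everywhere", {
  set.seed(12)
  for (i in 1:100) {
    b <- runif(1, 0.05, 5)
    f <- runif(1, 0.1, 10)
    cc <- 4 * b * runif(1, 0.05, 0.95) / f   # c*f < 4b
    p <- linlog_params(0, b, cc, f = f, log_d = runif(1, -2, 8))
    expect_identical(classify_regime(p), "monotone")
    grid <- seq(p$log_d / f - 50 / f, p$log_d / f + 50 / f, length.out = 200)
    expect_true(all(linlog_slope(p, grid) > 0))
  }
})

test_that("a huge logistic offset supplied as log_d stays usable", {
  # d = exp(500) overflows double; the log-scale carrier must not
  p <- linlog_params(a = 0, b = 0.1, c = 4, f = 0.2, log_d = 500)
  st <- stationary_points(p)
  expect_identical(st$regime, "two_points")
  expect_equal(st$rmax + st$rmin, 2 * 500 / 0.2, tolerance = 1e-9)
  expect_true(all(is.finite(linlog_eval(p, c(0, 2500, 5000)))))
})
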