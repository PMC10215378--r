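test_that("noiseless data from known parameters are recovered exactly", {
  d <- noiseless_ref_data()
  fit <- fit_linlog(d)
  truth <- ref_params()
  expect_true(fit$converged)
  for (nm in c("a", "b", "c", "f")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-4)
  }
  expect_equal(fit$params$log_d, truth$log_d, tolerance = 1e-4)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_identical(fit$stationary$regime, "two_points")
})

test_that("data on an exact line yield a monotone fit with r2 = 1", {
  x <- 1:8
  fit <- fit_linlog(dose_response(x, 2 + 3 * x))
  expect_true(fit$converged)
  expect_lte(fit$params$c * fit$params$f, 4 * fit$params$b)
  expect_identical(fit$stationary$regime, "monotone")
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("reported rss equals residuals recomputed through linlog_eval", {
  des <- synthetic_design(seed = 7)
  d <- generate_primary(des)
  fit <- fit_linlog(d)
  rss2 <- sum((d$response - linlog_eval(fit$params, d$dose))^2)
  expect_equal(fit$rss, rss2)
  expect_equal(fit$residuals, d$response - linlog_eval(fit$params, d$dose))
})

test_that("the fit is invariant to affine rescaling of the dose axis", {
  des <- synthetic_design(seed = 5)
  d <- generate_primary(des)
  fit0 <- fit_linlog(d)
  for (ab in list(c(10, 0), c(0.01, 0), c(2, -50))) {
    d2 <- dose_response(ab[1] * d$dose + ab[2], d$response)
    fit2 <- fit_linlog(d2)
    # same predictions at corresponding doses
    expect_equal(predict(fit2, ab[1] * d$dose + ab[2]), predict(fit0, d$dose),
                 tolerance = 1e-6)
    # stationary doses map through the same affine transform
    expect_equal(fit2$stationary$rmin,
                 ab[1] * fit0$stationary$rmin + ab[2],
                 tolerance = 1e-6)
    expect_equal(fit2$stationary$rmax,
                 ab[1] * fit0$stationary$rmax + ab[2],
                 tolerance = 1e-6)
  }
})

test_that("fit_linlog rejects undersized or constant data", {
  expect_error(fit_linlog(dose_response(1:4, c(1, 2, 3, 4))), "at least 5")
  expect_error(fit_linlog(dose_response(rep(1:2, 3), rep(1:2, 3) + 0.5)),
               "distinct dose")
  expect_error(fit_linlog(dose_response(1:6, rep(2, 6))), "constant")
})

test_that("seeded noisy recovery lands within 5% of the dose range", {
  des <- synthetic_design(seed = 1)  # 6 levels over 77-127, 8 reps, 3% noise
  d <- generate_primary(des)
  truth <- attr(d, "truth")
  fit <- fit_linlog(d)
  range_d <- des$dose_max - des$dose_min
  expect_identical(fit$stationary$regime, "two_points")
  expect_lte(abs(fit$stationary$rmin - truth$rmin), 0.05 * range_d)
  expect_lte(abs(fit$stationary$rmax - truth$rmax), 0.05 * range_d)
})

test_that("exact two-segment data are recovered to 1e-6", {
  x <- seq(1, 9, by = 0.5)
  y <- pmin(x, 5)
  fit <- fit_segmented(dose_response(x, y))
  expect_equal(fit$breakpoint, 5, tolerance = 1e-6)
  expect_equal(fit$pre_slope, 1, tolerance = 1e-6)
  expect_equal(fit$plateau, 5, tolerance = 1e-6)
  expect_identical(fit$orientation, "ascending-plateau")
  # flat-then-rising data pick the other orientation
  fit2 <- fit_segmented(dose_response(x, pmax(x, 5)))
  expect_equal(fit2$breakpoint, 5, tolerance = 1e-6)
  expect_identical(fit2$orientation, "plateau-ascending")
})

test_that("polished breakpoint beats a 1000-point grid search", {
  set.seed(31)
  for (i in 1:5) {
    x <- rep(seq(0, 10, length.out = 7), each = 3)
    y <- pmin(x, runif(1, 3, 8)) + rnorm(length(x), 0, 0.3)
    d <- dose_response(x, y)
    fit <- fit_segmented(d, orientation = "ascending-plateau")
    # independent grid-search oracle
    grid <- seq(min(x), max(x), length.out = 1000)
    grid_rss <- vapply(grid, function(bp) {
      z <- pmin(x, bp)
      sum(stats::lm.fit(cbind(1, z), y)$residuals^2)
    }, numeric(1))
    expect_lte(fit$rss, min(grid_rss) + 1e-9)
    expect_gte(fit$breakpoint, min(x))
    expect_lte(fit$breakpoint, max(x))
  }
})

test_that("noisy plateau data recover the breakpoint within 5% of range", {
  des <- synthetic_design(dose_min = 77, dose_max = 127, n_levels = 6,
                          reps_per_level = 8, noise_sd = 0.02, seed = 2)
  d <- generate_companion(des, anchor = 100, amplitude = 10)
  fit <- fit_segmented(d, orientation = "ascending-plateau")
  expect_lte(abs(fit$breakpoint - 100), 0.05 * (127 - 77))
})

test_that("constant-response segmented data are flagged degenerate", {
  fit <- fit_segmented(dose_response(1:6, rep(4, 6)))
  expect_true(fit$degenerate)
  expect_equal(fit$plateau, 4)
})

test_that("model selection picks the generating model on noiseless data", {
  sel1 <- fit_candidates(noiseless_ref_data())
  expect_identical(sel1$winner, "linear-logistic")
  x <- seq(1, 9, by = 0.5)
  sel2 <- fit_candidates(dose_response(x, pmin(x, 5)))
  expect_identical(sel2$winner, "linear-plateau")
  # single-candidate race
  sel3 <- fit_candidates(noiseless_ref_data(), candidates = "quadratic")
  expect_identical(sel3$winner, "quadratic")
  expect_true(is.na(sel3$delta_aicc))
  expect_error(fit_candidates(noiseless_ref_data(), candidates = character(0)),
               "empty")
  expect_error(fit_candidates(noiseless_ref_data(), candidates = "spline"),
               "unknown candidate")
})

test_that("candidates needing more observations than available are skipped", {
  d <- dose_response(1:5, c(1, 2.2, 2.9, 4.1, 5))
  sel <- fit_candidates(d)
  expect_true("linear-logistic" %in% sel$skipped)
  expect_false("linear-logistic" %in% sel$candidates$model)
  expect_gt(nrow(sel$candidates), 0)
})

test_that("dose normalization follows 100 * concentration / requirement", {
  expect_equal(normalize_dose(0.8, 1.0), 80)
  expect_equal(normalize_dose(1.0, 1.0), 100)
  expect_equal(normalize_dose(1.2, 0.8), 150)
  expect_equal(normalize_dose(c(0.5, 1.5), 1.25), c(40, 120))
  expect_error(normalize_dose(1, 0), "positive")
  expect_error(normalize_dose(1, -2), "positive")
})

test_that("nearest treatment mapping breaks ties toward the larger dose", {
  grid <- c(77, 87, 97, 107, 117, 127)
  expect_equal(nearest_treatment(116.2, grid), 117)
  expect_equal(nearest_treatment(112.0, c(107, 117)), 117)
  expect_equal(nearest_treatment(77.0, c(77, 87)), 77)
  expect_error(nearest_treatment(1, numeric(0)), "non-empty")
})
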