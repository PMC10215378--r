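test_that("zero-noise generation reproduces the mean curve exactly", {
  des <- synthetic_design(noise_sd = 0, seed = 1)
  d <- generate_primary(des)
  expect_equal(d$response, linlog_eval(default_truth_params(), d$dose))
  truth <- attr(d, "truth")
  st <- stationary_points(default_truth_params())
  expect_equal(truth$rmax, st$rmax)
  expect_equal(truth$rmin, st$rmin)
})

test_that("generators are pure functions of (design, params, seed)", {
  des <- synthetic_design(seed = 9)
  d1 <- generate_primary(des)
  d2 <- generate_primary(des)
  expect_identical(d1$response, d2$response)
  d3 <- generate_primary(des, seed = 10)
  expect_false(identical(d1$response, d3$response))
  c1 <- generate_companion(des, anchor = 100)
  c2 <- generate_companion(des, anchor = 100)
  expect_identical(c1$response, c2$response)
  # the generator restores the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_primary(des)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("per-level means obey the CLT bound at heavy replication", {
  des <- synthetic_design(reps_per_level = 200, noise_sd = 0.03, seed = 21)
  d <- generate_primary(des)
  truth <- attr(d, "truth")
  mu <- linlog_eval(truth$params, des$levels)
  means <- tapply(d$response, d$dose, mean)[as.character(des$levels)]
  expect_true(all(abs(as.numeric(means) - mu) <=
                    3 * truth$noise_sd / sqrt(200)))
})

test_that("generated tables satisfy the dose-response invariants", {
  des <- synthetic_design(seed = 2)
  for (tab in list(generate_primary(des),
                   generate_companion(des, anchor = 110))) {
    expect_s3_class(tab, "dose_response")
    expect_true(all(is.finite(tab$dose)))
    expect_true(all(is.finite(tab$response)))
    expect_equal(nrow(tab), des$n_levels * des$reps_per_level)
    expect_equal(length(unique(tab$dose)), des$n_levels)
  }
})

test_that("monotone generating parameters are refused with an explanation", {
  des <- synthetic_design()
  mono <- linlog_params(a = 0, b = 1, c = 2, d = 10, f = 1)  # c*f < 4b
  expect_error(generate_primary(des, mono), "c\\*f > 4b")
  # explicit opt-out still generates
  d <- generate_primary(des, mono, require_inflection = FALSE)
  expect_s3_class(d, "dose_response")
  # stationary doses must sit inside the design range
  narrow <- synthetic_design(dose_min = 90, dose_max = 100)
  expect_error(generate_primary(narrow), "outside the design range")
})

test_that("companion generation validates anchor and amplitude", {
  des <- synthetic_design()
  expect_error(generate_companion(des, anchor = 200), "within the dose range")
  expect_error(generate_companion(des, anchor = 100, amplitude = 0),
               "non-zero")
})

test_that("noiseless companion round-trips through the segmented fitter", {
  des <- synthetic_design(noise_sd = 0)
  d <- generate_companion(des, anchor = 105.3, amplitude = 8)
  fit <- fit_segmented(d, orientation = "ascending-plateau")
  expect_equal(fit$breakpoint, 105.3, tolerance = 1e-6)
  # logistic shape: midpoint at the anchor, rising curve
  d2 <- generate_companion(des, anchor = 105.3, amplitude = 8,
                           shape = "logistic-rise-at-anchor")
  mu <- d2$response[!duplicated(d2$dose)]  # levels are generated sorted
  expect_true(all(diff(mu) > 0))
})

test_that("recovery on noiseless cells is essentially exact", {
  des <- synthetic_design(noise_sd = 0)
  out <- recovery_study(des, n_sims = 10, seed = 5)
  range_d <- des$dose_max - des$dose_min
  expect_equal(out$failed, 0)
  expect_lte(abs(out$bias_rmin), 1e-6 * range_d)
  expect_lte(out$rmse_rmin, 1e-6 * range_d)
  expect_lte(abs(out$bias_rmax), 1e-6 * range_d)
  expect_lte(out$rmse_breakpoint, 1e-6 * range_d)
})

test_that("recovery_study can attach bootstrap coverage of Rmin", {
  des <- synthetic_design(seed = 3)
  out <- recovery_study(des, n_sims = 10, seed = 8, coverage = TRUE,
                        B = 50, alpha = 0.10)
  expect_true("rmin_coverage" %in% names(out))
  expect_gte(out$rmin_coverage, 0)
  expect_lte(out$rmin_coverage, 1)
})

test_that("doubling replication does not worsen RMSE (allowing MC noise)", {
  designs <- list(synthetic_design(reps_per_level = 4, seed = 1),
                  synthetic_design(reps_per_level = 8, seed = 1),
                  synthetic_design(reps_per_level = 16, seed = 1))
  out <- recovery_study(designs, n_sims = 30, seed = 17)
  # monotone non-increasing up to one Monte-Carlo violation of 10%
  ok <- diff(out$rmse_rmin) <= 0.1 * utils::head(out$rmse_rmin, -1)
  expect_gte(sum(ok), length(ok) - 1)
})
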