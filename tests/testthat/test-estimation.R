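test_that("chronological split keeps order and partitions the series", {
  s10 <- data.frame(day_index = 1:10, w = 0.5, p_obs = 1)
  sp <- split_learning_test(s10, 0.8)
  expect_equal(nrow(sp$learning), 8)
  expect_equal(nrow(sp$test), 2)
  s31 <- data.frame(day_index = 1:31, w = 0.5, p_obs = 1)
  sp31 <- split_learning_test(s31, 0.8) # floor(24.8) = 24
  expect_equal(nrow(sp31$learning), 24)
  expect_equal(nrow(sp31$test), 7)
  s30 <- data.frame(day_index = 1:30, w = 0.5, p_obs = 1)
  expect_equal(nrow(split_learning_test(s30, 0.8)$learning), 24)
  expect_error(split_learning_test(s10[1:4, ], 0.8), "at least 5")
  expect_error(split_learning_test(s10, 1.2), "fraction")
  # property: partition and order preservation over random lengths
  set.seed(15)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    f <- runif(1, 0.3, 0.9)
    s <- data.frame(day_index = sort(sample(1:200, n)), w = runif(n, 0.1, 1),
                    p_obs = runif(n, 0.1, 10))
    sp <- split_learning_test(s, f)
    expect_equal(rbind(sp$learning, sp$test), s, ignore_attr = TRUE)
    expect_equal(nrow(sp$learning), floor(f * n))
  }
})

test_that("original-model fit matches the closed form and an optimizer oracle", {
  # hand least squares: dK = (0.5*1.2 + 1.0*1.8) / (0.25 + 1.0) = 1.92
  fit <- fit_original(data.frame(day_index = 1:2, w = c(0.5, 1.0),
                                 p_obs = c(1.2, 1.8)))
  expect_equal(fit$parameters$K_a, 1.92)
  # exact proportional data: perfect fit
  w <- seq(0.1, 1, by = 0.1)
  exact <- fit_original(data.frame(day_index = 1:10, w = w, p_obs = 2 * w))
  expect_equal(exact$parameters$K_a, 2)
  expect_equal(exact$sse, 0)
  # iterative minimization oracle agrees to 1e-10
  set.seed(31)
  p_obs <- 1.4 * w + rnorm(10, 0, 0.2)
  f2 <- fit_original(data.frame(day_index = 1:10, w = w, p_obs = p_obs))
  oracle <- optimize(function(k) sum((p_obs - k * w)^2), c(-50, 50),
                     tol = 1e-12)$minimum
  expect_equal(f2$parameters$K_a, oracle, tolerance = 1e-10)
  expect_error(fit_original(data.frame(day_index = 1, w = 0, p_obs = 1)),
               "degenerate")
})

test_that("optimized fit recovers noise-free synthetic parameters", {
  truth <- toy_params()
  series <- toy_series(truth, n = 30, seed = 44)
  fit <- fit_optimized(series)
  expect_lt(fit$sse, 1e-8)
  tc <- canonicalize(truth)$summary
  fc <- fit$identifiable
  for (fld in c("a", "tau_a", "f", "tau_f", "delta_K", "delta_C")) {
    expect_equal(fc[[fld]], tc[[fld]], tolerance = 1e-3)
  }
  expect_equal(fit$rmse, sqrt(fit$sse / fit$n_learning))
  expect_lte(fit$r_squared, 1)
})

test_that("frozen fits predict without refitting", {
  truth <- toy_params()
  series <- toy_series(truth, n = 30, seed = 45)
  sp <- split_learning_test(series)
  fit <- fit_optimized(sp$learning)
  # noise-free generator/fitter consistency on held-out days
  expect_equal(predict(fit, sp$test), sp$test$p_obs, tolerance = 1e-6)
  # re-presenting a learning day reproduces its fitted value
  expect_equal(predict(fit, sp$learning[3, ]), sp$learning$p_obs[3],
               tolerance = 1e-6)
  # original-model predictions ignore the day index entirely
  fo <- fit_original(sp$learning)
  nd1 <- data.frame(day_index = 1, w = 0.6)
  nd2 <- data.frame(day_index = 999, w = 0.6)
  expect_identical(predict(fo, nd1), predict(fo, nd2))
  expect_error(predict(fit, data.frame(day_index = 5, w = NA_real_)),
               "missing load")
})

test_that("multistart SSE never increases with more starts and respects nesting", {
  set.seed(77)
  mk <- function(seed) {
    days <- sort(sample(1:80, 24))
    w <- runif(24, 0.1, 1)
    p <- evaluate_optimized(default_subject_parameters(1, seed)$S01, days, w) +
      rnorm(24, 0, 0.1)
    data.frame(day_index = days, w = w, p_obs = p)
  }
  for (seed in 1:5) {
    d <- mk(seed)
    f4 <- fit_optimized(d, fit_options(n_starts = 4, seed = 7))
    f16 <- fit_optimized(d, fit_options(n_starts = 16, seed = 7))
    expect_lte(f16$sse, f4$sse + 1e-12)
    forig <- fit_original(d)
    expect_lte(f16$sse, forig$sse + 1e-9)
  }
})

test_that("fit results survive a JSON round trip", {
  series <- toy_series(n = 25, seed = 46)
  fit <- fit_optimized(series)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- read_fit_result(path)
  expect_equal(back$sse, fit$sse)
  expect_equal(unclass(back$parameters), unclass(fit$parameters),
               tolerance = 1e-10)
  nd <- data.frame(day_index = c(2, 9), w = c(0.3, 0.8))
  expect_equal(predict(back, nd), predict(fit, nd), tolerance = 1e-10)
})

test_that("series extraction drops undefined days and enforces the floor", {
  co <- simulate_cohort(cohort_config(n_subjects = 1, weeks = 8, seed = 19))
  tab <- enrich_day_table(co$day_table)
  s <- subject_series(tab, "S01", "tl_hrv")
  expect_true(all(is.finite(s$p_obs)))
  expect_true(!is.unsorted(s$day_index, strictly = TRUE))
  small <- data.frame(day_index = 1:6, w = runif(6, 0.1, 1), p_obs = 1:6)
  expect_error(fit_optimized(small), "below the floor")
  expect_s3_class(fit_optimized(small, fit_options(min_observations = 5)),
                  "ffm_fit")
})
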