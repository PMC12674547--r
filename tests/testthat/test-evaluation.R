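test_that("fit metrics match hand values and a loop oracle", {
  o <- c(1, 2, 3)
  m <- fit_metrics(o, c(1, 2, 4))
  expect_equal(m$sse, 1)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r_squared, 0.5)
  perfect <- fit_metrics(o, o)
  expect_equal(unlist(perfect[c("sse", "rmse", "r_squared")]), c(0, 0, 1),
               ignore_attr = TRUE)
  # predicting the mean everywhere is the R^2 = 0 baseline
  expect_equal(fit_metrics(o, rep(mean(o), 3))$r_squared, 0)
  # constant observed series: R^2 flagged undefined, SSE/RMSE intact
  const <- fit_metrics(rep(2, 5), c(2, 2, 2, 2, 3))
  expect_true(is.na(const$r_squared))
  expect_equal(const$sse, 1)
  set.seed(23)
  for (i in 1:10) {
    o <- rnorm(sample(3:40, 1))
    p <- o + rnorm(length(o), 0, 0.5)
    got <- fit_metrics(o, p)
    want <- oracle_fit_metrics(o, p)
    expect_equal(got$sse, want$sse)
    expect_equal(got$rmse, want$rmse)
    expect_equal(got$r_squared, want$r_squared)
  }
})

test_that("prediction metrics compute MAPE with scale invariance", {
  pm <- prediction_metrics(c(100, 200), c(90, 220))
  expect_equal(pm$mape, 10)
  expect_equal(pm$ape, c(10, 10))
  expect_equal(prediction_metrics(c(1, 2), c(1, 2))$mape, 0)
  set.seed(24)
  o <- runif(15, 0.1, 10)
  p <- o * runif(15, 0.8, 1.2)
  expect_equal(prediction_metrics(o, p)$mape, oracle_mape(o, p))
  for (k in c(0.01, 3, 1000)) {
    expect_equal(prediction_metrics(k * o, k * p)$mape,
                 prediction_metrics(o, p)$mape)
  }
  expect_error(prediction_metrics(c(0, 1), c(1, 1)), "undefined")
})

test_that("horizon dependency uses exact permutation p for small samples", {
  # perfect concordance / discordance
  up <- temporal_dependency(c(61, 63, 66, 68, 70), 60, c(1, 2, 3, 4, 5))
  expect_equal(up$rho, 1)
  down <- temporal_dependency(c(61, 63, 66, 68, 70), 60, c(5, 4, 3, 2, 1))
  expect_equal(down$rho, -1)
  expect_equal(up$method, "exact permutation")
  # n = 5 with a known permutation matches exhaustive enumeration (120 orders)
  ape <- c(2.3, 0.7, 4.1, 1.9, 3.3)
  td <- temporal_dependency(c(62, 64, 67, 71, 75), 60, ape)
  expect_equal(td$p, oracle_spearman_p(c(2, 4, 7, 11, 15), ape))
  # large n: t-approximation, cross-checked against the stock test
  set.seed(26)
  days <- 60 + sort(sample(1:40, 12))
  ape12 <- runif(12, 0, 30)
  big <- temporal_dependency(days, 60, ape12)
  ref <- suppressWarnings(cor.test(days - 60, ape12, method = "spearman"))
  expect_equal(big$rho, unname(ref$estimate))
  expect_equal(big$method, "t approximation")
  expect_error(temporal_dependency(c(61, 62), 60, c(1, 2)), "at least 3")
  expect_error(temporal_dependency(c(59, 62, 64), 60, c(1, 2, 3)), "follow")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(27)
  x <- runif(9, 1, 50)
  y <- runif(9, 1, 50)
  base <- temporal_dependency(50 + sort(x), 50, y)$rho
  for (f in list(function(v) v^3, function(v) log(v), function(v) 10 * v + 2)) {
    expect_equal(temporal_dependency(50 + sort(x), 50, f(y))$rho, base)
  }
})

test_that("model comparison branches on normality and applies Bonferroni", {
  # approximately normal differences select the paired t branch
  set.seed(28)
  d <- rnorm(13, 0.5, 1)
  opt <- runif(13, 0.5, 0.9)
  cr <- compare_models(opt + d, opt, family_size = 3, metric_name = "r_squared")
  expect_equal(cr$test, "paired-t")
  expect_gte(cr$shapiro_p, 0.05)
  expect_equal(cr$p_corrected, min(1, 3 * cr$p_raw))
  expect_equal(cr$direction, sign(mean(d)))
  # strongly skewed differences select the Wilcoxon branch
  dskew <- c(rexp(12, 0.2), 40)
  crw <- compare_models(opt + dskew, opt, metric_name = "rmse")
  expect_equal(crw$test, "wilcoxon")
  expect_lt(crw$shapiro_p, 0.05)
  # identical vectors: degenerate flag, no test
  crd <- compare_models(opt, opt)
  expect_true(crd$degenerate)
  expect_equal(crd$test, "none")
  # Bonferroni cap and monotonicity in family size
  big <- compare_models(opt + rnorm(13, 0, 1), opt, family_size = 50)
  expect_lte(big$p_corrected, 1)
  for (m in 1:6) {
    cm <- compare_models(opt + d, opt, family_size = m)
    expect_equal(cm$p_corrected, min(1, m * cm$p_raw))
  }
  expect_error(compare_models(1:3, 1:2), "paired")
})

test_that("cohort summary reproduces the reference study characteristics", {
  tab <- reference_cohort()
  cs <- cohort_summary(tab)
  expect_equal(cs$n_subjects, 13)
  expect_equal(cs$total_paired_observations, 420)
  expect_equal(cs$mean$attendance_pct, 88.5, tolerance = 0.001)
  expect_equal(cs$sd$attendance_pct, 5.9, tolerance = 0.01)
  expect_equal(cs$mean$bmi, 23.07, tolerance = 0.001)
  expect_equal(cs$sd$bmi, 3.52, tolerance = 0.005)
  expect_equal(unname(cs$gender_pct["Female"]), 61.5, tolerance = 0.01)
  expect_equal(tab$actual_sessions[9], 28)
  expect_equal(tab$attendance_pct[9], 77.8)
  expect_error(cohort_summary(tab[0, ]), "empty")
})

test_that("per-subject evaluation runs the full chronological pipeline", {
  series <- toy_series(n = 30, seed = 50)
  series$p_obs <- series$p_obs + rnorm(30, 0, 0.03)
  ev <- evaluate_subject(series)
  expect_s3_class(ev$fit_optimized, "ffm_fit")
  expect_lte(ev$fit_optimized$sse, ev$fit_original$sse + 1e-9)
  expect_gte(ev$test_metrics_optimized$mape, 0)
  expect_true(all(ev$temporal_optimized$horizons > 0))
})
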