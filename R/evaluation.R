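#' Goodness-of-fit metrics
#'
#' `SSE = sum((o - p)^2)`, `RMSE = sqrt(SSE / n)`, and
#' `R^2 = 1 - SSE / sum((o - mean(o))^2)`. On a constant observed series the
#' total sum of squares is zero and `R^2` is returned as `NA` (flagged);
#' SSE and RMSE are still valid.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 1;
#'   `R^2` needs >= 2).
#' @return List with `sse`, `rmse`, `r_squared`, `n`.
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("fit_metrics: observed and predicted lengths differ", call. = FALSE)
  }
  n <- length(observed)
  if (n < 1L) stop("fit_metrics: empty input", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sse / tss
  list(sse = sse, rmse = sqrt(sse / n), r_squared = r2, n = n)
}

#' Prediction metrics on a held-out test set
#'
#' RMSE plus the mean absolute percentage error
#' `MAPE = (100 / n) * sum(|o - p| / |o|)`; the per-day absolute percentage
#' errors are retained for the prediction-horizon analysis. Normalized output
#' indicators are bounded below by 0.1, so the denominator can never be zero
#' on pipeline data; a zero observation raises an error regardless.
#'
#' @param observed,predicted Equal-length numeric vectors, length >= 1.
#' @return List of class `prediction_metrics`: `rmse`, `mape` (percent),
#'   `ape` (percent, per day), `n`.
#' @export
prediction_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("prediction_metrics: observed and predicted lengths differ",
         call. = FALSE)
  }
  if (length(observed) < 1L) stop("prediction_metrics: empty input",
                                  call. = FALSE)
  if (any(observed == 0)) {
    stop("prediction_metrics: observed value of 0 makes APE undefined",
         call. = FALSE)
  }
  ape <- 100 * abs(observed - predicted) / abs(observed)
  structure(list(rmse = sqrt(mean((observed - predicted)^2)),
                 mape = mean(ape), ape = ape, n = length(observed)),
            class = "prediction_metrics")
}

# Spearman rho on average ranks.
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Two-sided permutation p-value for Spearman rho: exact enumeration of all
# n! orderings for n <= n_exact, t-distribution approximation otherwise.
spearman_p <- function(x, y, n_exact = 8L) {
  n <- length(x)
  rho <- spearman_rho(x, y)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  if (n <= n_exact) {
    perms <- permutations_of(n)
    rx <- rank(x)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact permutation")
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2),
         method = "t approximation")
  }
}

# All n! permutations of 1..n as rows (n <= 8 -> at most 40320 rows).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Prediction-horizon dependency of test errors
#'
#' Spearman rank correlation between the prediction horizon (days elapsed
#' since the last learning-set session) and the absolute percentage error of
#' each test-day prediction. The p-value is exact (full permutation
#' enumeration) for 8 or fewer test days and uses the t approximation
#' otherwise; significance is assessed at p < 0.05.
#'
#' @param test_day_indices Day indices of the test sessions.
#' @param last_learning_day Day index of the final learning session.
#' @param ape_vector Absolute percentage errors, one per test day.
#' @return List with `horizons`, `rho`, `p`, `method`, `significant`.
#' @export
temporal_dependency <- function(test_day_indices, last_learning_day,
                                ape_vector) {
  horizons <- as.numeric(test_day_indices) - as.numeric(last_learning_day)
  if (length(horizons) < 3L) {
    stop("temporal_dependency: need at least 3 test days", call. = FALSE)
  }
  if (any(horizons <= 0)) {
    stop("temporal_dependency: all test days must follow the last learning day",
         call. = FALSE)
  }
  if (length(ape_vector) != length(horizons)) {
    stop("temporal_dependency: one APE per test day required", call. = FALSE)
  }
  sp <- spearman_p(horizons, ape_vector)
  list(horizons = horizons, rho = sp$rho, p = sp$p, method = sp$method,
       significant = is.finite(sp$p) && sp$p < 0.05)
}

#' Paired comparison of optimized versus original model metrics
#'
#' Given one metric value per subject under each model, tests the paired
#' differences `optimized - original`: Shapiro-Wilk normality check on the
#' differences, then a two-sided paired t-test when normality is not rejected
#' (p >= 0.05) or a Wilcoxon signed-rank test (zero differences discarded)
#' otherwise, with Bonferroni correction `p_corrected = min(1, m * p_raw)`.
#'
#' @param metric_optimized,metric_original Paired numeric vectors (one entry
#'   per subject); pairs with undefined entries are removed.
#' @param family_size Bonferroni family size `m` (default 3, one comparison
#'   per internal-load indicator).
#' @param metric_name Label carried into the result.
#' @return Object of class `comparison_result` with fields `metric`,
#'   `differences`, `n`, `shapiro_p`, `test`, `p_raw`, `p_corrected`,
#'   `family_size`, `mean_difference`, `direction`, `degenerate`.
#' @export
compare_models <- function(metric_optimized, metric_original, family_size = 3L,
                           metric_name = "metric") {
  if (length(metric_optimized) != length(metric_original)) {
    stop("compare_models: vectors must be paired (equal length)", call. = FALSE)
  }
  ok <- is.finite(metric_optimized) & is.finite(metric_original)
  d <- metric_optimized[ok] - metric_original[ok]
  if (length(d) < 4L) {
    stop("compare_models: need at least 4 defined pairs", call. = FALSE)
  }
  base <- list(metric = metric_name, differences = d, n = length(d),
               family_size = as.integer(family_size),
               mean_difference = mean(d),
               direction = sign(mean(d)))
  if (all(d == 0)) {
    return(structure(c(base, list(shapiro_p = NA_real_, test = "none",
                                  p_raw = NA_real_, p_corrected = NA_real_,
                                  degenerate = TRUE)),
                     class = "comparison_result"))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= 0.05) {
    ht <- stats::t.test(d, mu = 0)
    test <- "paired-t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(d, mu = 0))
    test <- "wilcoxon"
  }
  structure(c(base, list(shapiro_p = sw$p.value, test = test,
                         p_raw = ht$p.value,
                         p_corrected = min(1, family_size * ht$p.value),
                         degenerate = FALSE)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: all paired differences zero (no test performed)\n",
                x$metric))
    return(invisible(x))
  }
  cat(sprintf("%s: n = %d, mean diff = %.4g (%s), %s p = %.4g, Bonferroni (m = %d) p = %.4g\n",
              x$metric, x$n, x$mean_difference,
              if (x$direction >= 0) "optimized higher" else "optimized lower",
              x$test, x$p_raw, x$family_size, x$p_corrected))
  invisible(x)
}

#' Cohort summary statistics
#'
#' Column means and sample (n-1) standard deviations of the per-subject
#' characteristics table, gender shares, and the total number of paired
#' (external load, internal load) observations, which equals the sum of
#' attended sessions.
#'
#' @param subject_table `data.frame` with columns `age`, `gender`, `bmi`,
#'   `total_period_days`, `actual_sessions`, `attendance_pct` (see
#'   [reference_cohort()]).
#' @return List with `n_subjects`, `total_paired_observations`,
#'   `gender_pct` (named percentages), and per-column `mean`/`sd` lists.
#' @export
cohort_summary <- function(subject_table) {
  if (nrow(subject_table) == 0L) {
    stop("cohort_summary: empty subject table", call. = FALSE)
  }
  num_cols <- c("age", "bmi", "total_period_days", "actual_sessions",
                "attendance_pct")
  num_cols <- intersect(num_cols, names(subject_table))
  list(n_subjects = nrow(subject_table),
       total_paired_observations = sum(subject_table$actual_sessions),
       gender_pct = 100 * table(subject_table$gender) / nrow(subject_table),
       mean = lapply(subject_table[num_cols], mean),
       sd = lapply(subject_table[num_cols], stats::sd))
}

#' Reference cohort characteristics table
#'
#' Per-subject characteristics of the 13-subject, 12-week cycling cohort the
#' package's defaults emulate: age, gender, BMI, self-reported physical
#' activity level, total training period in days, attended sessions, and
#' attendance rate (percent of planned sessions).
#'
#' @return A 13-row `data.frame`.
#' @export
reference_cohort <- function() {
  data.frame(
    subject = 1:13,
    age = c(20, 23, 25, 25, 25, 18, 19, 19, 19, 19, 28, 19, 21),
    gender = c("Female", "Female", "Female", "Female", "Male", "Female",
               "Female", "Female", "Female", "Male", "Male", "Male", "Male"),
    bmi = c(22.08, 19.75, 23.80, 21.23, 25.86, 18.31, 21.01, 22.87, 19.96,
            23.15, 31.43, 27.41, 22.99),
    activity_level = c("Moderate", "High", "High", "Low", "Moderate", "High",
                       "Moderate", "High", "Moderate", "High", "High", "High",
                       "Low"),
    total_period_days = c(72, 79, 73, 71, 79, 72, 78, 76, 75, 75, 72, 75, 75),
    actual_sessions = c(31, 42, 32, 31, 34, 29, 32, 33, 28, 30, 32, 33, 33),
    attendance_pct = c(86.1, 100.0, 88.9, 86.1, 94.4, 80.6, 88.9, 91.7, 77.8,
                       83.3, 88.8, 91.7, 91.7))
}

#' Full per-subject evaluation of one indicator
#'
#' Convenience wrapper running the whole chronological pipeline for one
#' subject and indicator: split, fit both models, predict the test days, and
#' compute fit, prediction, and horizon-dependency summaries.
#'
#' @param series Subject series from [subject_series()].
#' @param split_fraction Learning fraction (default 0.8).
#' @param options [fit_options()] for the optimized model.
#' @return List with `fit_optimized`, `fit_original`, `test_metrics_optimized`,
#'   `test_metrics_original`, `temporal_optimized`, `split`.
#' @export
evaluate_subject <- function(series, split_fraction = 0.8,
                             options = fit_options()) {
  sp <- split_learning_test(series, split_fraction)
  fo <- fit_optimized(sp$learning, options)
  fg <- fit_original(sp$learning)
  po <- predict(fo, sp$test)
  pg <- predict(fg, sp$test)
  mo <- prediction_metrics(sp$test$p_obs, po)
  mg <- prediction_metrics(sp$test$p_obs, pg)
  td <- if (nrow(sp$test) >= 3L) {
    temporal_dependency(sp$test$day_index, max(sp$learning$day_index), mo$ape)
  } else NULL
  list(fit_optimized = fo, fit_original = fg,
       test_metrics_optimized = mo, test_metrics_original = mg,
       temporal_optimized = td, split = sp)
}
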