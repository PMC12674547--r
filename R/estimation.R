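#' Chronological learning/test split
#'
#' Splits a subject's ordered day series into the first `floor(fraction * n)`
#' observations (the learning set) and the remainder (the test set). With
#' fractional counts the learning set is rounded down so the test set is
#' never empty for `fraction < 1`.
#'
#' @param series `data.frame` ordered by `day_index` (checked).
#' @param fraction Learning fraction in (0, 1); default 0.8.
#' @return List with `learning` and `test` data frames.
#' @export
split_learning_test <- function(series, fraction = 0.8) {
  if (fraction <= 0 || fraction >= 1) {
    stop("split_learning_test: fraction must lie in (0, 1)", call. = FALSE)
  }
  n <- nrow(series)
  if (n < 5L) {
    stop("split_learning_test: need at least 5 observations", call. = FALSE)
  }
  if (is.unsorted(series$day_index, strictly = TRUE)) {
    stop("split_learning_test: series must be strictly increasing in day_index",
         call. = FALSE)
  }
  k <- floor(fraction * n)
  list(learning = series[seq_len(k), , drop = FALSE],
       test = series[seq(k + 1L, n), , drop = FALSE])
}

# Residuals of the identifiable 6-parameter form
# theta = (a, tau_a, f, tau_f, delta_K, delta_C)
ffm_residuals <- function(theta, t, w, p_obs) {
  pred <- theta[1] * exp(-theta[2] * t) - theta[3] * exp(-theta[4] * t) +
    theta[5] * w + theta[6]
  p_obs - pred
}

theta_to_parameters <- function(theta) {
  ffm_parameters(a = theta[1], tau_a = theta[2], K_a = theta[5], C1 = theta[6],
                 f = theta[3], tau_f = theta[4], K_f = 0, C2 = 0)
}

#' Fitting options for the optimized model
#'
#' @param n_starts Number of seeded multistarts (default 32).
#' @param seed Integer seed for start generation.
#' @param tau_bounds Bounds on both decay rates, per day.
#' @param coef_bound Symmetric bound on `|a|`, `|f|`, `|delta_K|`, `|delta_C|`.
#' @param min_observations Minimum learning observations required.
#' @return List of class `fit_options`.
#' @export
fit_options <- function(n_starts = 32L, seed = 7L,
                        tau_bounds = c(1e-4, 5), coef_bound = 100,
                        min_observations = 10L) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 tau_bounds = tau_bounds, coef_bound = coef_bound,
                 min_observations = as.integer(min_observations)),
            class = "fit_options")
}

# Multistart initial points: log-uniform decay rates within bounds, standard
# normal draws for the linear coefficients. Start 0 is always the original
# model's closed-form solution (a = f = 0), which guarantees the fitted SSE
# never exceeds the nested original model's SSE.
make_starts <- function(n_starts, seed, tau_bounds, p_obs, w) {
  rng <- local_rng(seed)
  on.exit(rng())
  lt <- log(tau_bounds)
  dk0 <- sum(p_obs * w) / sum(w^2)
  starts <- vector("list", n_starts)
  starts[[1]] <- c(0, exp(mean(lt)), 0, exp(mean(lt)), dk0, 0)
  for (i in seq_len(n_starts - 1L)) {
    starts[[i + 1L]] <- c(stats::rnorm(1), exp(stats::runif(1, lt[1], lt[2])),
                          stats::rnorm(1), exp(stats::runif(1, lt[1], lt[2])),
                          stats::rnorm(1), stats::rnorm(1))
  }
  starts
}

#' Fit the optimized fitness-fatigue model to a learning series
#'
#' Minimizes the sum of squared errors between observed output indicators and
#' the model over the 6-dimensional identifiable parameterization
#' `(a, tau_a, f, tau_f, delta_K, delta_C)`, using bounded
#' Levenberg-Marquardt least squares ([minpack.lm::nls.lm]) from `n_starts`
#' seeded initial points; the best (lowest-SSE) converged solution is
#' returned. Decay rates are bounded to `tau_bounds` and linear coefficients
#' to `[-coef_bound, coef_bound]`. Parameters are reported in 8-coefficient
#' form under the convention `K_f = 0`, `C2 = 0` (only the differences are
#' identifiable) and canonicalized so `tau_f >= tau_a`.
#'
#' @param learning `data.frame` with columns `day_index`, `w`, `p_obs`
#'   (see [subject_series()]).
#' @param options A [fit_options()] object.
#' @return Object of class `ffm_fit` carrying `model = "optimized"`, the
#'   fitted [ffm_parameters()], the canonical [identifiable_summary()], `sse`,
#'   `rmse`, `r_squared`, `n_learning`, `best_start`, and per-start
#'   convergence codes.
#' @export
fit_optimized <- function(learning, options = fit_options()) {
  t <- learning$day_index
  w <- learning$w
  p_obs <- learning$p_obs
  ok <- is.finite(t) & is.finite(w) & is.finite(p_obs)
  if (any(!ok)) {
    message(sprintf("fit_optimized: dropping %d day(s) with undefined values",
                    sum(!ok)))
    t <- t[ok]; w <- w[ok]; p_obs <- p_obs[ok]
  }
  if (length(p_obs) < options$min_observations) {
    stop(sprintf("fit_optimized: %d observations below the floor of %d",
                 length(p_obs), options$min_observations), call. = FALSE)
  }
  lb <- c(-options$coef_bound, options$tau_bounds[1],
          -options$coef_bound, options$tau_bounds[1],
          -options$coef_bound, -options$coef_bound)
  ub <- c(options$coef_bound, options$tau_bounds[2],
          options$coef_bound, options$tau_bounds[2],
          options$coef_bound, options$coef_bound)
  starts <- make_starts(options$n_starts, options$seed, options$tau_bounds,
                        p_obs, w)
  best <- NULL
  best_sse <- Inf
  best_i <- NA_integer_
  codes <- integer(length(starts))
  for (i in seq_along(starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lb, upper = ub,
                         fn = ffm_residuals, t = t, w = w, p_obs = p_obs,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) { codes[i] <- -1L; next }
    codes[i] <- res$info
    sse <- sum(res$fvec^2)
    if (is.finite(sse) && sse < best_sse) {
      best_sse <- sse
      best <- res
      best_i <- i
    }
  }
  if (is.null(best)) {
    stop("fit_optimized: no multistart converged; convergence codes: ",
         paste(codes, collapse = ","), call. = FALSE)
  }
  canon <- canonicalize(theta_to_parameters(best$par))
  m <- fit_metrics(p_obs, p_obs - ffm_residuals(best$par, t, w, p_obs))
  structure(list(model = "optimized",
                 parameters = canon$params,
                 identifiable = canon$summary,
                 sse = m$sse, rmse = m$rmse, r_squared = m$r_squared,
                 n_learning = length(p_obs),
                 best_start = best_i,
                 convergence_codes = codes),
            class = "ffm_fit")
}

#' Fit the original load-proportional model
#'
#' Closed-form least squares through the origin:
#' `delta_K = sum(p_obs * w) / sum(w^2)`, reported as `K_a = delta_K`,
#' `K_f = 0`.
#'
#' @param learning `data.frame` with columns `day_index`, `w`, `p_obs`.
#' @return Object of class `ffm_fit` with `model = "original"`.
#' @export
fit_original <- function(learning) {
  w <- learning$w
  p_obs <- learning$p_obs
  ok <- is.finite(w) & is.finite(p_obs)
  w <- w[ok]; p_obs <- p_obs[ok]
  if (length(w) < 1L || all(w == 0)) {
    stop("fit_original: degenerate design (no non-zero loads)", call. = FALSE)
  }
  dk <- sum(p_obs * w) / sum(w^2)
  m <- fit_metrics(p_obs, dk * w)
  structure(list(model = "original",
                 parameters = original_parameters(K_a = dk, K_f = 0),
                 sse = m$sse, rmse = m$rmse, r_squared = m$r_squared,
                 n_learning = length(p_obs),
                 best_start = 1L, convergence_codes = 0L),
            class = "ffm_fit")
}

#' @export
print.ffm_fit <- function(x, ...) {
  cat(sprintf("%s model fit: n = %d, SSE = %.4g, RMSE = %.4g, R^2 = %s\n",
              x$model, x$n_learning, x$sse, x$rmse,
              if (is.na(x$r_squared)) "undefined" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Predict held-out performance from a frozen fit
#'
#' Evaluates the fitted parameters at each test day's `(t, w)` without any
#' refitting. The original model depends on `w` only.
#'
#' @param object An `ffm_fit`.
#' @param newdata `data.frame` with columns `day_index` and `w`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ffm_fit <- function(object, newdata, ...) {
  if (any(!is.finite(newdata$w))) {
    bad <- newdata$day_index[!is.finite(newdata$w)]
    stop("predict.ffm_fit: missing load w on day(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (object$model == "optimized") {
    evaluate_optimized(object$parameters, t = newdata$day_index, w = newdata$w)
  } else {
    evaluate_original(object$parameters, w = newdata$w)
  }
}

#' Extract one subject/indicator series from an enriched day table
#'
#' Selects the subject's rows, renames the chosen `p_obs_<indicator>` column
#' to `p_obs` and `W_norm` to `w`, drops days with undefined values (with a
#' message), and checks chronology.
#'
#' @param day_table Enriched day table (see [enrich_day_table()]).
#' @param subject Subject id.
#' @param indicator One of `"hrr1_delta"`, `"hrr_pct"`, `"tl_hrv"`.
#' @return `data.frame` with columns `subject_id`, `day_index`, `w`, `p_obs`.
#' @export
subject_series <- function(day_table, subject,
                           indicator = c("hrr1_delta", "hrr_pct", "tl_hrv")) {
  indicator <- match.arg(indicator)
  col <- paste0("p_obs_", indicator)
  if (!col %in% names(day_table)) {
    stop("subject_series: day table lacks column ", col,
         "; run enrich_day_table() first", call. = FALSE)
  }
  df <- day_table[day_table$subject_id == subject, , drop = FALSE]
  df <- df[order(df$day_index), , drop = FALSE]
  out <- data.frame(subject_id = df$subject_id, day_index = df$day_index,
                    w = df$W_norm, p_obs = df[[col]])
  drop <- !is.finite(out$p_obs) | !is.finite(out$w)
  if (any(drop)) {
    message(sprintf("subject_series: dropped %d day(s) with undefined %s",
                    sum(drop), indicator))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Serialize a fit result to JSON
#'
#' @param fit An `ffm_fit`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "ffm_fit"))
  payload <- list(model = fit$model,
                  parameters = unclass(fit$parameters),
                  sse = fit$sse, rmse = fit$rmse, r_squared = fit$r_squared,
                  n_learning = fit$n_learning, best_start = fit$best_start,
                  convergence_codes = fit$convergence_codes)
  if (!is.null(fit$identifiable)) payload$identifiable <- unclass(fit$identifiable)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Read a fit result written by [write_fit_result()]
#'
#' @param path JSON path.
#' @return An `ffm_fit` object.
#' @export
read_fit_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- if (x$model == "optimized") {
    do.call(ffm_parameters, x$parameters[c("a", "tau_a", "K_a", "C1",
                                           "f", "tau_f", "K_f", "C2")])
  } else {
    original_parameters(K_a = x$parameters$K_a, K_f = x$parameters$K_f)
  }
  out <- list(model = x$model, parameters = pars,
              sse = x$sse, rmse = x$rmse, r_squared = x$r_squared,
              n_learning = x$n_learning, best_start = x$best_start,
              convergence_codes = x$convergence_codes)
  if (!is.null(x$identifiable)) {
    out$identifiable <- structure(as.list(x$identifiable),
                                  class = "ffm_identifiable")
  }
  structure(out, class = "ffm_fit")
}
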