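#' External load from ergometer speed and resistance streams
#'
#' Integrates the product of instantaneous speed and resistance level over the
#' session. With 1 Hz sampling the integral is the rectangular (1 s) sum of
#' elementwise products.
#'
#' @param speed_series Numeric vector, 1 Hz speed samples.
#' @param resistance_series Numeric vector, 1 Hz resistance-level samples;
#'   must match `speed_series` in length.
#' @return The external load `W_raw` (device units x seconds).
#' @export
#' @examples
#' compute_external_load(rep(2, 10), rep(3, 10)) # 60
compute_external_load <- function(speed_series, resistance_series) {
  if (length(speed_series) == 0L) {
    stop("compute_external_load: empty input series", call. = FALSE)
  }
  if (length(speed_series) != length(resistance_series)) {
    stop("compute_external_load: speed and resistance series differ in length",
         call. = FALSE)
  }
  sum(as.numeric(speed_series) * as.numeric(resistance_series))
}

#' RMSSD of an R-R interval sequence
#'
#' Root mean square of successive differences of adjacent R-R intervals, the
#' standard vagally mediated short-term HRV measure.
#'
#' @param rr_ms Numeric vector of R-R intervals in milliseconds, length >= 2.
#' @return RMSSD in milliseconds.
#' @export
#' @examples
#' compute_rmssd(c(800, 810, 790)) # sqrt(250)
compute_rmssd <- function(rr_ms) {
  if (length(rr_ms) < 2L) {
    stop("compute_rmssd: need at least 2 R-R intervals", call. = FALSE)
  }
  d <- diff(as.numeric(rr_ms))
  sqrt(mean(d^2))
}

#' Heart-rate-recovery indicators from post-exercise heart rate
#'
#' From the final training minute and the first five post-exercise minutes of
#' 1 Hz heart rate, computes:
#' * `hr_peak` — maximum heart rate over the final training minute;
#' * `hrr1` — mean heart rate over post-exercise seconds 1-60;
#' * `hr_stage1` — mean heart rate over post-exercise seconds 1-15 (window
#'   mean; set `stage1_mode = "instant"` to use the single second-15 sample);
#' * `hrr1_delta` — `hr_peak - hrr1`, the 1-minute heart-rate recovery (bpm);
#' * `hrr_pct` — `100 * (hr_stage1 - hrr1) / hr_stage1`, the fractional drop
#'   relative to the early post-exercise level (percent).
#'
#' @param hr_final_minute Numeric vector of length 60 (last training minute,
#'   1 Hz, bpm).
#' @param hr_post_5min Numeric vector, first post-exercise seconds at 1 Hz
#'   (length >= 60).
#' @param stage1_mode `"mean"` (default) or `"instant"`.
#' @return Named list with the five quantities above.
#' @export
compute_hrr_indicators <- function(hr_final_minute, hr_post_5min,
                                   stage1_mode = c("mean", "instant")) {
  stage1_mode <- match.arg(stage1_mode)
  if (length(hr_final_minute) != 60L) {
    stop("compute_hrr_indicators: final-minute series must have 60 samples",
         call. = FALSE)
  }
  if (length(hr_post_5min) < 60L) {
    stop("compute_hrr_indicators: post-exercise series must have >= 60 samples",
         call. = FALSE)
  }
  if (any(hr_final_minute <= 0) || any(hr_post_5min <= 0)) {
    stop("compute_hrr_indicators: heart rate must be positive", call. = FALSE)
  }
  hr_peak <- max(hr_final_minute)
  hrr1 <- mean(hr_post_5min[1:60])
  hr_stage1 <- if (stage1_mode == "mean") mean(hr_post_5min[1:15]) else
    hr_post_5min[15]
  if (hr_stage1 == 0) {
    stop("compute_hrr_indicators: HR at stage 1 is zero", call. = FALSE)
  }
  list(hr_peak = hr_peak,
       hrr1 = hrr1,
       hr_stage1 = hr_stage1,
       hrr1_delta = hr_peak - hrr1,
       hrr_pct = 100 * (hr_stage1 - hrr1) / hr_stage1)
}

#' HRV-based internal training load
#'
#' Ratio of the immediate RMSSD perturbation to the 30-minute recovery span:
#' `(pre5 - post5) / (post30 - post5)`, computed on raw RMSSD values (ms) from
#' the three 5-minute seated rest windows around a session.
#'
#' @param pre5_rmssd,post5_rmssd,post30_rmssd RMSSD (ms) of the pre-training,
#'   immediate post-training, and 30-minute post-training windows.
#' @return Dimensionless internal-load value. Negative values (post-30 RMSSD
#'   below the immediate post value) are passed through unchanged.
#' @export
#' @examples
#' compute_tl_hrv(50, 20, 40) # 1.5
compute_tl_hrv <- function(pre5_rmssd, post5_rmssd, post30_rmssd) {
  if (any(c(pre5_rmssd, post5_rmssd, post30_rmssd) < 0)) {
    stop("compute_tl_hrv: RMSSD values must be non-negative", call. = FALSE)
  }
  if (post30_rmssd == post5_rmssd) {
    stop("compute_tl_hrv: undefined indicator (post30 RMSSD equals post5); ",
         "flag this day for exclusion", call. = FALSE)
  }
  (pre5_rmssd - post5_rmssd) / (post30_rmssd - post5_rmssd)
}

#' Normalize a series to the 0.1-1 interval
#'
#' Affine map `v' = 0.1 + 0.9 (v - min) / (max - min)`. The lower bound of
#' 0.1 (rather than 0) keeps the normalized internal load strictly positive so
#' the output indicator, a ratio, can never divide by zero.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @param allow_constant If `TRUE`, a constant series maps to the interval
#'   midpoint 0.55 instead of raising an error.
#' @return Numeric vector in \[0.1, 1\], order-preserving.
#' @export
#' @examples
#' normalize_unit_interval(c(2, 4, 6)) # 0.10 0.55 1.00
normalize_unit_interval <- function(values, allow_constant = FALSE) {
  values <- as.numeric(values)
  if (sum(is.finite(values)) < 2L) {
    stop("normalize_unit_interval: need at least 2 finite values",
         call. = FALSE)
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    if (!allow_constant) {
      stop("normalize_unit_interval: constant series has no scale; ",
           "set allow_constant = TRUE to map all values to 0.55",
           call. = FALSE)
    }
    return(rep(0.55, length(values)))
  }
  0.1 + 0.9 * (values - rng[1]) / (rng[2] - rng[1])
}

#' Daily output indicator: normalized external over internal load
#'
#' The performance proxy observed on each training day is the ratio of the
#' day's normalized external load to its normalized internal-load indicator.
#' Because both inputs live in \[0.1, 1\], the ratio is bounded in \[0.1, 10\].
#'
#' @param w_norm Normalized external load in \[0.1, 1\].
#' @param i_norm Normalized internal-load indicator in \[0.1, 1\].
#' @return `w_norm / i_norm`, vectorized.
#' @export
compute_output_indicator <- function(w_norm, i_norm) {
  eps <- 1e-12
  if (any(w_norm < 0.1 - eps | w_norm > 1 + eps) ||
      any(i_norm < 0.1 - eps | i_norm > 1 + eps)) {
    stop("compute_output_indicator: inputs must be normalized to [0.1, 1]",
         call. = FALSE)
  }
  w_norm / i_norm
}

#' Derive a day-level observation table from session records
#'
#' Applies the indicator pipeline to a list of session records (see
#' [read_session_streams()] or [simulate_session_streams()]): external load
#' from the speed/resistance streams, the two HRR indicators from the final
#' training minute and post-exercise heart rate, and the HRV load from the
#' three rest-window RMSSDs. Days whose HRV load is undefined (equal post5 and
#' post30 RMSSD) are dropped with a message.
#'
#' @param sessions List of `session_record` objects.
#' @return Day table `data.frame` with columns `subject_id`, `day_index`,
#'   `session_index`, `W_raw`, `hrr1_delta`, `hrr_pct`, `tl_hrv`.
#' @export
build_day_table <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    hrr <- compute_hrr_indicators(s$hr_final_minute, s$hr_post_5min)
    tl <- tryCatch(
      compute_tl_hrv(compute_rmssd(s$rr_pre5),
                     compute_rmssd(s$rr_post5),
                     compute_rmssd(s$rr_post30)),
      error = function(e) NA_real_)
    data.frame(subject_id = s$subject_id,
               day_index = s$day_index,
               W_raw = compute_external_load(s$speed_series, s$resistance_series),
               hrr1_delta = hrr$hrr1_delta,
               hrr_pct = hrr$hrr_pct,
               tl_hrv = tl)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$day_index), , drop = FALSE]
  n_bad <- sum(is.na(out$tl_hrv))
  if (n_bad > 0) {
    message(sprintf("build_day_table: %d day(s) with undefined HRV load kept as NA",
                    n_bad))
  }
  out$session_index <- stats::ave(out$day_index, out$subject_id,
                                  FUN = seq_along)
  rownames(out) <- NULL
  out[, c("subject_id", "day_index", "session_index", "W_raw",
          "hrr1_delta", "hrr_pct", "tl_hrv")]
}

#' Append normalized loads and output indicators to a day table
#'
#' For each subject, normalizes the external load and each available internal
#' indicator to \[0.1, 1\] and appends the per-indicator output column
#' `p_obs_<indicator> = W_norm / <indicator>_norm`. By default normalization
#' uses the subject's full series (learning and test days alike), matching the
#' study design of normalizing before splitting; `scope = "learning"`
#' restricts the min/max to the first `split_fraction` of days to avoid using
#' any test-day information (the normalization map is then applied to all
#' days, and values are clipped to \[0.1, 1\]).
#'
#' @param day_table Day table as produced by [build_day_table()] or
#'   [read_day_table()].
#' @param indicators Character vector of indicator columns to process.
#' @param scope `"all"` (default) or `"learning"`.
#' @param split_fraction Learning fraction used when `scope = "learning"`.
#' @return The day table with `W_norm`, `<indicator>_norm` and
#'   `p_obs_<indicator>` columns appended.
#' @export
enrich_day_table <- function(day_table,
                             indicators = c("hrr1_delta", "hrr_pct", "tl_hrv"),
                             scope = c("all", "learning"),
                             split_fraction = 0.8) {
  scope <- match.arg(scope)
  indicators <- intersect(indicators, names(day_table))
  norm_col <- function(v, idx_ref) {
    ref <- v[idx_ref]
    ref <- ref[is.finite(ref)]
    rng <- range(ref)
    if (rng[1] == rng[2]) return(rep(NA_real_, length(v)))
    pmin(1, pmax(0.1, 0.1 + 0.9 * (v - rng[1]) / (rng[2] - rng[1])))
  }
  parts <- lapply(split(day_table, day_table$subject_id), function(df) {
    df <- df[order(df$day_index), , drop = FALSE]
    n <- nrow(df)
    idx_ref <- if (scope == "learning") seq_len(max(2L, floor(split_fraction * n)))
      else seq_len(n)
    df$W_norm <- norm_col(df$W_raw, idx_ref)
    for (ind in indicators) {
      nc <- paste0(ind, "_norm")
      df[[nc]] <- norm_col(df[[ind]], idx_ref)
      df[[paste0("p_obs_", ind)]] <- df$W_norm / df[[nc]]
    }
    df
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
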