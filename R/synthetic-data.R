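#' Cohort configuration for the synthetic training study
#'
#' Defaults mirror the reference study design: 13 subjects completing 12
#' weeks of medium-intensity continuous cycling at 3 sessions per week, with
#' mean attendance of 88.5% of planned sessions.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param weeks Training weeks (>= 1).
#' @param sessions_per_week Planned sessions per week (>= 1).
#' @param attendance_rate Fraction of planned sessions attended, in (0, 1].
#' @param seed Integer seed driving schedule realization.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 13, weeks = 12, sessions_per_week = 3,
                          attendance_rate = 0.885, seed = 1L) {
  if (n_subjects < 1 || weeks < 1 || sessions_per_week < 1) {
    stop("cohort_config: n_subjects, weeks and sessions_per_week must be >= 1",
         call. = FALSE)
  }
  if (attendance_rate <= 0 || attendance_rate > 1) {
    stop("cohort_config: attendance_rate must lie in (0, 1]", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 weeks = as.integer(weeks),
                 sessions_per_week = as.integer(sessions_per_week),
                 attendance_rate = attendance_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Noise model for synthetic data
#'
#' Additive Gaussian noise on the day-level performance observation, plus iid
#' Gaussian jitter on simulated R-R intervals. For iid jitter the expected
#' RMSSD of a window equals `sd * sqrt(2)`, which is what makes the generator
#' calibratable against target RMSSD values.
#'
#' @param day_level_sd Standard deviation of the additive noise on P (>= 0).
#' @param rr_jitter_sd Standard deviation (ms) of R-R jitter used when a
#'   session spec carries no RMSSD target (>= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(day_level_sd = 0.05, rr_jitter_sd = 0) {
  if (day_level_sd < 0 || rr_jitter_sd < 0) {
    stop("noise_model: standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(day_level_sd = day_level_sd, rr_jitter_sd = rr_jitter_sd),
            class = "noise_model")
}

# Planned session grid: sessions_per_week evenly spaced days within each
# 7-day week (3/week -> Mon/Wed/Fri pattern), day 1 = first planned session.
planned_session_days <- function(weeks, sessions_per_week) {
  offsets <- round(seq(0, 4, length.out = sessions_per_week))
  if (sessions_per_week == 1L) offsets <- 0L
  as.integer(outer(offsets, (seq_len(weeks) - 1L) * 7L, "+") + 1L)
}

#' Generate attended-session schedules for a cohort
#'
#' Each subject attends `round(attendance_rate * planned)` sessions, drawn
#' uniformly without replacement from the planned weekly grid and returned in
#' chronological order. Day indices are rebased so each subject's first
#' attended session falls on day 1. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()] object.
#' @return Named list (one element per subject id `S01`, `S02`, ...) of
#'   strictly increasing integer day vectors.
#' @export
generate_schedule <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  planned <- sort(planned_session_days(config$weeks, config$sessions_per_week))
  n_attend <- round(config$attendance_rate * length(planned))
  if (n_attend < 1) {
    stop("generate_schedule: attendance rate leaves no sessions", call. = FALSE)
  }
  rng <- local_rng(config$seed)
  out <- lapply(seq_len(config$n_subjects), function(i) {
    days <- sort(sample(planned, n_attend))
    as.integer(days - days[1] + 1L)
  })
  rng()
  names(out) <- sprintf("S%02d", seq_len(config$n_subjects))
  out
}

# Seeded RNG scope: saves the caller's RNG state, seeds, and returns a
# restore function so package randomness never perturbs the user's stream.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
    invisible(NULL)
  }
}

#' Plausible per-subject ground-truth model parameters
#'
#' Draws canonical parameter sets for simulation studies: slow adaptation
#' decay (`tau_a` ~ U(0.02, 0.08) per day), faster fatigue decay (`tau_f` ~
#' U(0.15, 0.40) per day), specificity coefficients ~ U(0.6, 1.4), and
#' identifiable gains `delta_K` ~ U(0.3, 0.8), `delta_C` ~ U(0.1, 0.4)
#' reported under the `K_f = 0`, `C2 = 0` convention. On a 12-week horizon
#' these produce visible early-period transients and a stable late period.
#'
#' @param n_subjects Number of parameter sets.
#' @param seed Integer seed.
#' @return Named list of [ffm_parameters()] objects.
#' @export
default_subject_parameters <- function(n_subjects = 13, seed = 1L) {
  rng <- local_rng(seed)
  out <- lapply(seq_len(n_subjects), function(i) {
    ffm_parameters(a = stats::runif(1, 0.6, 1.4),
                   tau_a = stats::runif(1, 0.02, 0.08),
                   K_a = stats::runif(1, 0.3, 0.8),
                   C1 = stats::runif(1, 0.1, 0.4),
                   f = stats::runif(1, 0.6, 1.4),
                   tau_f = stats::runif(1, 0.15, 0.40),
                   K_f = 0, C2 = 0)
  })
  rng()
  names(out) <- sprintf("S%02d", seq_len(n_subjects))
  out
}

#' Simulate a subject's day-level performance series
#'
#' Evaluates the optimized model at each attended day's `(t, w)` and adds
#' day-level Gaussian noise. The noise-free channel is returned alongside so
#' estimation tests can check exact recovery.
#'
#' @param params An [ffm_parameters()] object (ground truth).
#' @param schedule Strictly increasing integer day indices.
#' @param loads Normalized external loads `w`, one per scheduled day.
#' @param noise A [noise_model()] object.
#' @param seed Integer seed for the day-level noise.
#' @return `data.frame` with columns `day_index`, `w`, `p_true`, `p_obs`.
#' @export
simulate_day_series <- function(params, schedule, loads,
                                noise = noise_model(), seed = 1L) {
  stopifnot(inherits(params, "ffm_parameters"), inherits(noise, "noise_model"))
  if (any(diff(schedule) <= 0)) {
    stop("simulate_day_series: schedule days must be strictly increasing",
         call. = FALSE)
  }
  if (length(loads) != length(schedule)) {
    stop("simulate_day_series: one load per scheduled day required",
         call. = FALSE)
  }
  p_true <- evaluate_optimized(params, t = schedule, w = loads)
  rng <- local_rng(seed)
  eps <- if (noise$day_level_sd > 0)
    stats::rnorm(length(p_true), 0, noise$day_level_sd) else rep(0, length(p_true))
  rng()
  data.frame(day_index = as.integer(schedule), w = as.numeric(loads),
             p_true = p_true, p_obs = p_true + eps)
}

#' Session specification for stream simulation
#'
#' @param subject_id Subject identifier.
#' @param day_index Calendar day within the training period (first session 1).
#' @param rest_hr Resting heart rate (bpm), 0 < rest_hr < hr_max.
#' @param hr_max Individual maximal heart rate (bpm).
#' @param target_rmssd_pre,target_rmssd_post,target_rmssd_post30 Target RMSSD
#'   (ms) for the three rest windows; `NA` falls back to the noise model's
#'   `rr_jitter_sd`.
#' @param duration_s Training duration in seconds (default 1800 = 30 min).
#' @param mean_speed,mean_resistance Constant device speed / resistance level
#'   held during the session.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(subject_id, day_index, rest_hr = 65, hr_max = 195,
                         target_rmssd_pre = 45, target_rmssd_post = 18,
                         target_rmssd_post30 = 38,
                         duration_s = 1800, mean_speed = 20,
                         mean_resistance = 5) {
  if (rest_hr <= 0 || rest_hr >= hr_max) {
    stop("session_spec: need 0 < rest_hr < hr_max", call. = FALSE)
  }
  structure(list(subject_id = subject_id, day_index = as.integer(day_index),
                 rest_hr = rest_hr, hr_max = hr_max,
                 target_rmssd_pre = target_rmssd_pre,
                 target_rmssd_post = target_rmssd_post,
                 target_rmssd_post30 = target_rmssd_post30,
                 duration_s = as.integer(duration_s),
                 mean_speed = mean_speed,
                 mean_resistance = mean_resistance),
            class = "session_spec")
}

# R-R window: base interval from the window heart rate plus iid jitter whose
# sd = target_rmssd / sqrt(2), so the expected RMSSD matches the target.
simulate_rr_window <- function(hr_bpm, target_rmssd, fallback_sd, n = 300L) {
  base <- 60000 / rep_len(hr_bpm, n)
  sd <- if (is.finite(target_rmssd)) target_rmssd / sqrt(2) else fallback_sd
  jitter <- if (sd > 0) stats::rnorm(n, 0, sd) else rep(0, n)
  base + jitter
}

#' Simulate one session's wearable-style streams
#'
#' Emits 1 Hz speed and resistance for the training phase; heart rate ramps
#' linearly from 60% to 85% of `hr_max` so the final-minute peak hits the
#' submaximal target; post-exercise heart rate follows a single-exponential
#' recovery `rest_hr + (peak - rest_hr) * exp(-s / tau_rec)`; and each of the
#' three 5-minute rest windows yields an R-R sequence whose expected RMSSD
#' matches its target (jitter sd = target / sqrt(2)).
#'
#' @param spec A [session_spec()] object.
#' @param noise A [noise_model()] object.
#' @param seed Integer seed.
#' @param tau_rec Heart-rate recovery time constant in seconds.
#' @return An object of class `session_record` with fields `subject_id`,
#'   `day_index`, `speed_series`, `resistance_series`, `hr_train`,
#'   `hr_final_minute`, `hr_post_5min`, `rr_pre5`, `rr_post5`, `rr_post30`.
#' @export
simulate_session_streams <- function(spec, noise = noise_model(), seed = 1L,
                                     tau_rec = 60) {
  stopifnot(inherits(spec, "session_spec"), inherits(noise, "noise_model"))
  if (spec$duration_s < 120L) {
    stop("simulate_session_streams: session shorter than 120 s; ",
         "final-minute peak undefined", call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng())
  dur <- spec$duration_s
  hr_peak <- 0.85 * spec$hr_max
  hr_train <- 0.60 * spec$hr_max +
    (hr_peak - 0.60 * spec$hr_max) * (seq_len(dur) - 1) / (dur - 1)
  s <- seq_len(300L)
  hr_post <- spec$rest_hr + (hr_peak - spec$rest_hr) * exp(-s / tau_rec)
  hr_post30_win <- spec$rest_hr + 0.05 * (hr_peak - spec$rest_hr)
  # post5 R-R window uses the mid-recovery heart rate level
  hr_post5_win <- mean(hr_post)
  rec <- list(
    subject_id = spec$subject_id,
    day_index = spec$day_index,
    speed_series = rep(spec$mean_speed, dur),
    resistance_series = rep(spec$mean_resistance, dur),
    hr_train = hr_train,
    hr_final_minute = hr_train[(dur - 59L):dur],
    hr_post_5min = hr_post,
    rr_pre5 = simulate_rr_window(spec$rest_hr, spec$target_rmssd_pre,
                                 noise$rr_jitter_sd),
    rr_post5 = simulate_rr_window(hr_post5_win, spec$target_rmssd_post,
                                  noise$rr_jitter_sd),
    rr_post30 = simulate_rr_window(hr_post30_win, spec$target_rmssd_post30,
                                   noise$rr_jitter_sd))
  structure(rec, class = "session_record")
}

#' Simulate a full synthetic cohort
#'
#' Generates attended-session schedules, per-session wearable streams with
#' subject-specific baselines (resting heart rate, HR max, RMSSD levels,
#' ergometer settings varying day to day), the derived day table, and the
#' ground-truth model parameters used by day-level simulation studies.
#'
#' @param config A [cohort_config()] object.
#' @param noise A [noise_model()] object.
#' @return A list of class `synthetic_cohort` with elements `config`,
#'   `schedule`, `sessions` (list of `session_record`), `day_table`, `truth`
#'   (named list of [ffm_parameters()]), and `noise`.
#' @export
simulate_cohort <- function(config = cohort_config(), noise = noise_model()) {
  stopifnot(inherits(config, "cohort_config"))
  schedule <- generate_schedule(config)
  truth <- default_subject_parameters(config$n_subjects, seed = config$seed + 1L)
  rng <- local_rng(config$seed + 2L)
  sessions <- list()
  for (i in seq_along(schedule)) {
    sid <- names(schedule)[i]
    rest_hr <- stats::runif(1, 55, 75)
    hr_max <- stats::runif(1, 185, 205)
    rmssd_pre <- stats::runif(1, 35, 60)
    for (d in schedule[[i]]) {
      sp <- session_spec(
        subject_id = sid, day_index = d,
        rest_hr = rest_hr, hr_max = hr_max,
        target_rmssd_pre = rmssd_pre * stats::runif(1, 0.85, 1.15),
        target_rmssd_post = rmssd_pre * stats::runif(1, 0.30, 0.50),
        target_rmssd_post30 = rmssd_pre * stats::runif(1, 0.70, 0.95),
        mean_speed = stats::runif(1, 16, 26),
        mean_resistance = sample(3:8, 1))
      # per-session autonomic recovery speed varies day to day
      sessions[[length(sessions) + 1L]] <-
        simulate_session_streams(sp, noise,
                                 seed = sample.int(.Machine$integer.max, 1),
                                 tau_rec = stats::runif(1, 40, 90))
    }
  }
  rng()
  day_table <- if (length(sessions)) build_day_table(sessions) else
    empty_day_table()
  structure(list(config = config, schedule = schedule, sessions = sessions,
                 day_table = day_table, truth = truth, noise = noise),
            class = "synthetic_cohort")
}

empty_day_table <- function() {
  data.frame(subject_id = character(), day_index = integer(),
             session_index = integer(), W_raw = numeric(),
             hrr1_delta = numeric(), hrr_pct = numeric(), tl_hrv = numeric())
}

#' Write a synthetic cohort to disk as a fixture bundle
#'
#' Emits the long-format session-stream CSV, the day table CSV, and a
#' ground-truth JSON (per-subject parameters plus noise settings). All files
#' are round-trippable by [read_session_streams()] / [read_day_table()].
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("write_fixture_bundle: cannot create output directory ", out_dir,
         call. = FALSE)
  }
  paths <- c(streams = file.path(out_dir, "session_streams.csv"),
             day_table = file.path(out_dir, "day_table.csv"),
             truth = file.path(out_dir, "ground_truth.json"))
  write_session_streams(cohort$sessions, paths[["streams"]])
  write_day_table(cohort$day_table, paths[["day_table"]])
  truth <- lapply(cohort$truth, unclass)
  jsonlite::write_json(list(parameters = truth, noise = unclass(cohort$noise)),
                       paths[["truth"]], auto_unbox = TRUE, digits = 12)
  invisible(paths)
}
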