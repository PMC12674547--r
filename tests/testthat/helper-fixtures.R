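# Shared fixtures and independent oracles used across the suite.

toy_params <- function() {
  ffm_parameters(a = 1, tau_a = 0.05, K_a = 0.6, C1 = 0.4,
                 f = 1, tau_f = 0.2, K_f = 0.3, C2 = 0.2)
}

# A deterministic noise-free subject series from known parameters.
toy_series <- function(params = toy_params(), n = 20, seed = 1) {
  set.seed(seed)
  days <- sort(sample(1:60, n))
  w <- runif(n, 0.1, 1)
  data.frame(day_index = days, w = w,
             p_obs = evaluate_optimized(params, days, w))
}

# Brute-force loop oracle for the external-load integral.
oracle_external_load <- function(speed, resistance) {
  total <- 0
  for (i in seq_along(speed)) total <- total + speed[i] * resistance[i]
  total
}

# Brute-force loop oracles for the evaluation metrics.
oracle_fit_metrics <- function(o, p) {
  sse <- 0
  for (i in seq_along(o)) sse <- sse + (o[i] - p[i])^2
  tss <- 0
  for (i in seq_along(o)) tss <- tss + (o[i] - mean(o))^2
  list(sse = sse, rmse = sqrt(sse / length(o)), r_squared = 1 - sse / tss)
}

oracle_mape <- function(o, p) {
  s <- 0
  for (i in seq_along(o)) s <- s + abs(o[i] - p[i]) / abs(o[i])
  100 * s / length(o)
}

# Independent recursive permutation generator (list of index vectors).
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (rest in oracle_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(rest, n, after = pos)
    }
  }
  out
}

# Exhaustive two-sided permutation p-value for Spearman rho.
oracle_spearman_p <- function(x, y) {
  rho_obs <- cor(rank(x), rank(y))
  rhos <- vapply(oracle_permutations(length(y)),
                 function(idx) cor(rank(x), rank(y)[idx]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# A post-exercise heart-rate series with prescribed stage-1 (s 1-15) and
# first-minute (s 1-60) means.
hr_post_series <- function(stage1_mean, minute_mean, length_s = 300) {
  tail_mean <- (60 * minute_mean - 15 * stage1_mean) / 45
  c(rep(stage1_mean, 15), rep(tail_mean, 45), rep(minute_mean * 0.8, length_s - 60))
}
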