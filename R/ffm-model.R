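#' Construct an optimized fitness-fatigue parameter set
#'
#' The optimized model expresses daily performance as the difference between
#' an adaptation component and a fatigue component, each built from a decaying
#' exponential in calendar time plus an instantaneous gain on the day's
#' normalized external load:
#'
#' \deqn{P_n = (a e^{-\tau_a t} + K_a W_n + C_1) - (f e^{-\tau_f t} + K_f W_n + C_2)}
#'
#' `a` and `f` are specificity coefficients scaling the individual's
#' adaptation/fatigue decay curves; `tau_a` and `tau_f` are decay rates per
#' day; `K_a` and `K_f` are gains per unit of normalized load; `C1` and `C2`
#' are integration constants estimated alongside the other coefficients.
#'
#' Only the differences `K_a - K_f` and `C1 - C2` (and the exponential pair)
#' affect predictions; see [canonicalize()] and [identifiable_summary()].
#'
#' @param a,f Specificity coefficients (dimensionless, unconstrained sign).
#' @param tau_a,tau_f Decay rates per day; must be strictly positive.
#' @param K_a,K_f Load gain coefficients.
#' @param C1,C2 Integration constants.
#' @return An object of class `ffm_parameters`.
#' @export
#' @examples
#' p <- ffm_parameters(a = 1, tau_a = 0.05, K_a = 0.6, C1 = 0.4,
#'                     f = 1, tau_f = 0.2, K_f = 0.3, C2 = 0.2)
#' evaluate_optimized(p, t = 1, w = 1)
ffm_parameters <- function(a, tau_a, K_a, C1, f, tau_f, K_f, C2) {
  vals <- c(a = a, tau_a = tau_a, K_a = K_a, C1 = C1,
            f = f, tau_f = tau_f, K_f = K_f, C2 = C2)
  if (any(!is.finite(vals))) {
    stop("ffm_parameters: all coefficients must be finite", call. = FALSE)
  }
  if (tau_a <= 0 || tau_f <= 0) {
    stop("ffm_parameters: decay rates tau_a and tau_f must be > 0",
         call. = FALSE)
  }
  structure(as.list(vals), class = "ffm_parameters")
}

#' @export
print.ffm_parameters <- function(x, ...) {
  cat("Optimized fitness-fatigue parameters:\n")
  cat(sprintf("  adaptation: a = %.4g, tau_a = %.4g /day, K_a = %.4g, C1 = %.4g\n",
              x$a, x$tau_a, x$K_a, x$C1))
  cat(sprintf("  fatigue:    f = %.4g, tau_f = %.4g /day, K_f = %.4g, C2 = %.4g\n",
              x$f, x$tau_f, x$K_f, x$C2))
  invisible(x)
}

#' Construct original (load-proportional) model parameters
#'
#' The original model has no time dependence: \eqn{P_n = K_a W_n - K_f W_n}.
#' Only the difference `K_a - K_f` is identifiable from data.
#'
#' @param K_a,K_f Gain coefficients for adaptation and fatigue.
#' @return An object of class `original_parameters`.
#' @export
original_parameters <- function(K_a, K_f = 0) {
  if (!is.finite(K_a) || !is.finite(K_f)) {
    stop("original_parameters: gains must be finite", call. = FALSE)
  }
  structure(list(K_a = K_a, K_f = K_f), class = "original_parameters")
}

#' Identifiable parameter combination of the optimized model
#'
#' Because adding a common constant to both gains, or to both integration
#' constants, leaves every prediction unchanged, the model's predictions are
#' determined by six quantities: the exponential pair `(a, tau_a, f, tau_f)`
#' and the differences `delta_K = K_a - K_f`, `delta_C = C1 - C2`.
#'
#' @param params An [ffm_parameters()] object.
#' @return An object of class `ffm_identifiable` with fields
#'   `a`, `tau_a`, `f`, `tau_f`, `delta_K`, `delta_C`.
#' @export
identifiable_summary <- function(params) {
  stopifnot(inherits(params, "ffm_parameters"))
  structure(list(a = params$a, tau_a = params$tau_a,
                 f = params$f, tau_f = params$tau_f,
                 delta_K = params$K_a - params$K_f,
                 delta_C = params$C1 - params$C2),
            class = "ffm_identifiable")
}

#' Evaluate the optimized fitness-fatigue model
#'
#' Computes daily performance as the adaptation/fatigue difference, exactly in
#' the closed form documented under [ffm_parameters()]. Vectorized over `t`
#' and `w` (recycled to a common length).
#'
#' @param params An [ffm_parameters()] object.
#' @param t Day index within the training period (first session day is 1).
#' @param w Normalized external load, nominally in \[0.1, 1\].
#' @return Numeric vector of performance values.
#' @export
evaluate_optimized <- function(params, t, w) {
  comp <- evaluate_components(params, t, w)
  comp$adaptation - comp$fatigue
}

#' Evaluate the adaptation and fatigue components separately
#'
#' @inheritParams evaluate_optimized
#' @return A list with numeric vectors `adaptation` and `fatigue`; their
#'   difference equals [evaluate_optimized()] exactly.
#' @export
evaluate_components <- function(params, t, w) {
  stopifnot(inherits(params, "ffm_parameters"))
  if (params$tau_a <= 0 || params$tau_f <= 0) {
    stop("evaluate_components: decay rates must be > 0", call. = FALSE)
  }
  n <- max(length(t), length(w))
  t <- rep_len(as.numeric(t), n)
  w <- rep_len(as.numeric(w), n)
  list(adaptation = params$a * exp(-params$tau_a * t) + params$K_a * w + params$C1,
       fatigue    = params$f * exp(-params$tau_f * t) + params$K_f * w + params$C2)
}

#' Evaluate the original load-proportional model
#'
#' @param params An [original_parameters()] object.
#' @param w Normalized external load.
#' @return Numeric vector `(K_a - K_f) * w`; no time dependence.
#' @export
evaluate_original <- function(params, w) {
  stopifnot(inherits(params, "original_parameters"))
  (params$K_a - params$K_f) * as.numeric(w)
}

#' Canonicalize an optimized parameter set
#'
#' The two exponential components can be relabelled without changing any
#' prediction: swapping the decay rates while negating both specificity
#' coefficients (`a' = -f`, `tau_a' = tau_f`, `f' = -a`, `tau_f' = tau_a`)
#' leaves \eqn{a e^{-\tau_a t} - f e^{-\tau_f t}} intact. The canonical form
#' puts the faster decay in the fatigue slot (`tau_f >= tau_a`), matching the
#' physiological reading that fatigue dissipates at least as fast as
#' adaptation. An exact rate tie is resolved by requiring `|a| >= |f|`.
#'
#' @param params An [ffm_parameters()] object.
#' @return A list with elements `params` (canonical `ffm_parameters`) and
#'   `summary` (the [identifiable_summary()] of the canonical form).
#' @export
canonicalize <- function(params) {
  stopifnot(inherits(params, "ffm_parameters"))
  swap <- params$tau_a > params$tau_f ||
    (params$tau_a == params$tau_f && abs(params$a) < abs(params$f))
  out <- if (swap) {
    ffm_parameters(a = -params$f, tau_a = params$tau_f,
                   K_a = params$K_a, C1 = params$C1,
                   f = -params$a, tau_f = params$tau_a,
                   K_f = params$K_f, C2 = params$C2)
  } else {
    params
  }
  list(params = out, summary = identifiable_summary(out))
}

#' Serialize fitness-fatigue parameters to JSON
#'
#' Writes the eight coefficients under their standard names, a `canonical`
#' flag, and the identifiable summary.
#'
#' @param params An [ffm_parameters()] object.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_ffm_parameters <- function(params, path = NULL) {
  stopifnot(inherits(params, "ffm_parameters"))
  canon <- canonicalize(params)
  payload <- c(unclass(params),
               list(canonical = identical(unclass(canon$params), unclass(params)),
                    identifiable = unclass(canon$summary)))
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 12))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}

#' Read fitness-fatigue parameters from JSON
#'
#' @param path File written by [write_ffm_parameters()].
#' @return An [ffm_parameters()] object.
#' @export
read_ffm_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ffm_parameters(a = x$a, tau_a = x$tau_a, K_a = x$K_a, C1 = x$C1,
                 f = x$f, tau_f = x$tau_f, K_f = x$K_f, C2 = x$C2)
}
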