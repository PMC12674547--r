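Package: fitfatigue
Title: Fitness-Fatigue Modelling of Training Effectiveness from Wearable-Style Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying training effectiveness in recreational
    endurance training with an optimized fitness-fatigue impulse-response
    model. Computes external load from ergometer speed/resistance streams and
    internal load from heart-rate-variability (RMSSD) and heart-rate-recovery
    indicators, normalizes both to the 0.1-1 interval, fits per-subject model
    parameters on a chronological learning split by bounded multistart
    nonlinear least squares, predicts held-out sessions, and runs the full
    evaluation battery (R-squared/SSE/RMSE, MAPE, prediction-horizon rank
    correlation, paired optimized-versus-original model comparison with
    Bonferroni correction). A seeded synthetic-cohort generator emulates
    wearable session streams so every stage is testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
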