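# Shared fixtures: built once per test run and reused across files.

# Fast estimator configuration for repeated simulation runs.
fast_cfg <- function(...) {
  args <- utils::modifyList(
    list(K = 2, delta = 0.5,
         q_roster = default_roster(fast = TRUE),
         g_roster = default_roster(fast = TRUE),
         marginals = FALSE),
    list(...)
  )
  do.call(shift_config, args)
}

# One large draw from the generative model with strong synergy, plus
# well-specified nuisance fits; reused by several estimation tests.
dgm_large <- simulate_dataset(sim_scenario(n = 2000, synergy = 0.60,
                                           seed = 2024))
dgm_Q <- fit_outcome_regression(dgm_large, roster = default_roster(fast = TRUE),
                                seed = 1)
dgm_ratios <- fit_pair_ratios(dgm_large, c("A1", "A2"), c(0.5, 0.5),
                              method = "classifier",
                              roster = default_roster(fast = TRUE), seed = 2)

# Small deterministic tabular dataset.
tiny_dataset <- function(n = 30, binary = FALSE, seed = 7) {
  set.seed(seed)
  df <- data.frame(w1 = rnorm(n), w2 = rnorm(n),
                   a1 = rnorm(n, 2), a2 = rnorm(n, 2))
  df$y <- if (binary) rbinom(n, 1, 0.5) else rnorm(n, df$a1)
  mixture_dataset(df, covariates = c("w1", "w2"),
                  exposures = c("a1", "a2"), outcome = "y")
}

# Outcome model with an arbitrary closed-form prediction rule, for exact
# algebraic checks of the g-computation contrasts (no fitting, no bounding
# within the range used by the tests).
analytic_outcome_model <- function(predict_fun, exposures, covariates,
                                   y_range = c(-1e3, 1e3)) {
  structure(
    list(sel = list(fit = NULL,
                    predict_fun = function(fit, X) predict_fun(X),
                    learner = "analytic"),
         y_lo = y_range[1], y_hi = y_range[2], binary = FALSE,
         exposures = exposures, covariates = covariates),
    class = "outcome_model"
  )
}

# Closed-form Gaussian density-ratio oracle for a standard-normal exposure
# shifted by delta: g(a - delta) / g(a).
gaussian_ratio_oracle <- function(a, delta, mu = 0, sigma = 1) {
  exp((2 * delta * (a - mu) - delta^2) / (2 * sigma^2))
}

# Independent standard-normal draw with one exposure, no confounding.
gaussian_exposure_data <- function(n, seed = 5, p = 1) {
  set.seed(seed)
  df <- data.frame(w1 = rnorm(n))
  for (j in seq_len(p)) df[[paste0("a", j)]] <- rnorm(n)
  df$y <- rnorm(n)
  mixture_dataset(df, covariates = "w1",
                  exposures = paste0("a", seq_len(p)), outcome = "y")
}
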