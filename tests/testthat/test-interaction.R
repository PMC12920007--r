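make_fake_estimate <- function(psi, eif) {
  inf <- eif_inference(eif, psi)
  structure(list(psi = psi, eif = eif, se = inf$se, ci_lo = inf$ci_lo,
                 ci_hi = inf$ci_hi, p_value = inf$p_value, delta = 0.5,
                 n = length(eif), fold = NA_integer_, condition = "x"),
            class = "shift_estimate")
}

test_that("delta-method combination is the exact linear contrast", {
  set.seed(2)
  n <- 50
  a <- make_fake_estimate(1.4, rnorm(n))
  b <- make_fake_estimate(0.6, rnorm(n))
  cc <- make_fake_estimate(0.9, rnorm(n))
  # baseline chosen so additivity holds exactly: psi0 = b + c - a
  d0 <- make_fake_estimate(0.6 + 0.9 - 1.4, rnorm(n))
  est <- interaction_delta_method(a, b, cc, d0)
  expect_equal(est$psi_int, 0)
  expect_equal(est$eif, a$eif - b$eif - cc$eif + d0$eif)
  expect_error(interaction_delta_method(a, b, cc, make_fake_estimate(0, rnorm(9))),
               "misaligned")
})

test_that("variance adds across independent components", {
  n <- 300
  # orthogonal block EIFs: zero empirical covariance by construction
  e1 <- c(rep(c(1, -1), n / 2))
  e2 <- c(rep(c(1, 1, -1, -1), n / 4)) * sqrt(2)
  stopifnot(abs(sum(e1 * e2)) < 1e-12)
  a <- make_fake_estimate(1, e1)
  b <- make_fake_estimate(0.2, e2)
  zero <- make_fake_estimate(0, rep(0, n))
  est <- interaction_delta_method(a, b, zero, zero)
  expect_equal(stats::var(est$eif), stats::var(e1) + stats::var(e2),
               tolerance = 1e-10)
})

test_that("combined clever covariate has the inclusion-exclusion form", {
  h1 <- c(1.2, 0.8, 1.0)
  h2 <- c(0.9, 1.1, 1.0)
  # zero shifts: all ratios 1, H* identically 0
  expect_equal(combined_clever_covariate(rep(1, 3), rep(1, 3), rep(1, 3)),
               rep(0, 3))
  # independent exposures: H_joint = H_i H_j so H* = (H_i - 1)(H_j - 1)
  expect_equal(combined_clever_covariate(h1 * h2, h1, h2),
               (h1 - 1) * (h2 - 1))
  # Gaussian oracle value at the means, delta = +0.5 on both
  r <- gaussian_ratio_oracle(0, 0.5)
  expect_equal(combined_clever_covariate(r * r, r, r), (r - 1)^2)
  expect_equal((exp(-0.125) - 1)^2, 0.0138, tolerance = 1e-3)
  expect_error(combined_clever_covariate(h1, h2, c(1, 1)), "length")
})

test_that("direct-targeting TMLE recovers the built-in synergy", {
  est_dir <- tmle_interaction_direct(dgm_large, c("A1", "A2"), c(0.5, 0.5),
                                     dgm_Q, dgm_ratios)
  expect_lt(abs(est_dir$psi_int - 0.15), 3 * est_dir$se)
  # score equation solved on the rescaled outcome
  scale <- dgm_Q$y_hi - dgm_Q$y_lo
  expect_lt(abs(mean(est_dir$eif)) / scale, 1e-6)
  # agreement with the delta-method combination
  est_dm <- interaction_delta_method(
    tmle_shift_mean(dgm_large, shift_spec(c("A1", "A2"), 0.5), dgm_Q,
                    dgm_ratios$joint),
    tmle_shift_mean(dgm_large, shift_spec("A1", 0.5), dgm_Q, dgm_ratios$i),
    tmle_shift_mean(dgm_large, shift_spec("A2", 0.5), dgm_Q, dgm_ratios$j),
    baseline_mean(dgm_large), pair = c("A1", "A2"))
  expect_lt(abs(est_dm$psi_int - 0.15), 3 * est_dm$se)
  expect_lt(abs(est_dir$psi_int - est_dm$psi_int),
            2 * max(est_dir$se, est_dm$se))
})

test_that("zero shifts give exactly zero interaction", {
  d <- subset_rows(dgm_large, 1:400)
  zero_ratios <- list(
    joint = fit_conditional_density(d, shift_spec(c("A1", "A2"), 0), seed = 1),
    i = fit_conditional_density(d, shift_spec("A1", 0), seed = 1),
    j = fit_conditional_density(d, shift_spec("A2", 0), seed = 1)
  )
  est <- tmle_interaction_direct(d, c("A1", "A2"), c(0, 0), dgm_Q, zero_ratios)
  expect_equal(est$psi_int, 0)
  expect_equal(est$epsilon, 0)
})

test_that("g-computation contrasts obey exact algebra", {
  d <- tiny_dataset(n = 50)
  # additive fit: main-terms GLM has no product terms, contrast is zero
  Q_add <- fit_outcome_regression(d, roster = "glm", seed = 1)
  expect_equal(gcomp_interaction(Q_add, d, c("a1", "a2"), c(0.5, 0.7)), 0,
               tolerance = 1e-10)
  # pure product surface: contrast = beta * delta_i * delta_j for any data
  Q_prod <- analytic_outcome_model(
    function(X) 1.3 * X[, "a1"] * X[, "a2"],
    exposures = c("a1", "a2"), covariates = c("w1", "w2"))
  expect_equal(gcomp_interaction(Q_prod, d, c("a1", "a2"), c(0.5, 0.7)),
               1.3 * 0.5 * 0.7, tolerance = 1e-8)
  # DGM with its true mean surface: closed form synergy * delta_i * delta_j
  sc <- sim_scenario(n = 1000, synergy = 0.25, seed = 5)
  dd <- simulate_dataset(sc)
  Q_true <- analytic_outcome_model(
    function(X) 1 + 0.3 * X[, "W1"] + 0.2 * X[, "W2"] + 0.3 * X[, "A1"] +
      0.2 * X[, "A2"] - 0.3 * X[, "A3"] + 0.25 * X[, "A1"] * X[, "A2"] -
      0.20 * X[, "A5"] * X[, "A6"] + 0.2 * X[, "A4"]^2,
    exposures = dd$exposures, covariates = dd$covariates)
  expect_equal(gcomp_interaction(Q_true, dd, c("A1", "A2"), c(0.5, 0.5)),
               0.0625, tolerance = 1e-10)
})

test_that("three-way contrast annihilates lower-order surfaces", {
  d <- tiny_dataset(n = 40)
  d3 <- local({
    set.seed(1)
    df <- data.frame(w1 = rnorm(40), a1 = rnorm(40), a2 = rnorm(40),
                     a3 = rnorm(40))
    df$y <- rnorm(40)
    mixture_dataset(df, "w1", c("a1", "a2", "a3"), "y")
  })
  trip <- c("a1", "a2", "a3")
  dl <- c(0.5, 0.4, 0.3)
  Q_pair <- analytic_outcome_model(
    function(X) 2 * X[, "a1"] * X[, "a2"] - X[, "a2"] * X[, "a3"] +
      0.5 * X[, "a1"],
    exposures = trip, covariates = "w1")
  expect_equal(gcomp_threeway(Q_pair, d3, trip, dl), 0, tolerance = 1e-8)
  Q_trip <- analytic_outcome_model(
    function(X) 0.7 * X[, "a1"] * X[, "a2"] * X[, "a3"],
    exposures = trip, covariates = "w1")
  expect_equal(gcomp_threeway(Q_trip, d3, trip, dl),
               0.7 * prod(dl), tolerance = 1e-8)
  Q_add <- analytic_outcome_model(
    function(X) X[, "a1"] + 2 * X[, "a2"] - X[, "a3"],
    exposures = trip, covariates = "w1")
  expect_equal(gcomp_threeway(Q_add, d3, trip, dl), 0, tolerance = 1e-8)
})

test_that("interaction is null when the DGM has no product terms", {
  sc <- sim_scenario(n = 1500, synergy = 0, antagonism = 0, seed = 77)
  d <- simulate_dataset(sc)
  Q <- fit_outcome_regression(d, roster = default_roster(fast = TRUE),
                              seed = 1)
  ratios <- fit_pair_ratios(d, c("A1", "A2"), c(0.5, 0.5),
                            roster = default_roster(fast = TRUE), seed = 2)
  est <- tmle_interaction_direct(d, c("A1", "A2"), c(0.5, 0.5), Q, ratios)
  expect_lt(abs(est$psi_int), 2 * est$se + 0.02)
})
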