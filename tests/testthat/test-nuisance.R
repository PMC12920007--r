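test_that("outcome regression: discrete selection, scaling and degeneracy", {
  d <- tiny_dataset(n = 40)
  # mean-only roster: predictions constant at the sample mean
  Q <- fit_outcome_regression(d, roster = "mean", seed = 1)
  expect_equal(unique(predict(Q, d)), mean(d$Y), tolerance = 1e-10)
  # continuous scaling constants: min - m, max + m with m = 0.1 range
  m <- 0.1 * diff(range(d$Y))
  expect_equal(Q$y_lo, min(d$Y) - m)
  expect_equal(Q$y_hi, max(d$Y) + m)
  # binary outcome: unit scaling
  db <- tiny_dataset(n = 40, binary = TRUE)
  Qb <- fit_outcome_regression(db, roster = c("mean", "glm"), seed = 1)
  expect_equal(c(Qb$y_lo, Qb$y_hi), c(0, 1))
  # degenerate outcome rejected
  dd <- tiny_dataset(n = 20)
  dd$Y <- rep(1, 20)
  expect_error(fit_outcome_regression(dd, roster = "mean"), "degenerate")
})

test_that("CV selects the well-specified form and recovers coefficients", {
  d <- dgm_large
  Q <- dgm_Q
  expect_equal(Q$sel$learner, "glm_twoway")
  # independent OLS oracle with the correct parametric terms on this draw
  df <- data.frame(d$W, d$A, Y = d$Y)
  ols <- stats::lm(Y ~ W1 + W2 + A1 + A2 + A3 + A1:A2 + A5:A6 + I(A4^2),
                   data = df)
  sm <- summary(ols)$coefficients
  truth <- c(A1 = 0.3, A2 = 0.2, A3 = -0.3)
  for (nm in names(truth)) {
    expect_lt(abs(sm[nm, "Estimate"] - truth[[nm]]), 3 * sm[nm, "Std. Error"])
  }
  # the selected fit reproduces the oracle's response surface
  rmse <- sqrt(mean((predict(Q, d) - unname(stats::predict(ols)))^2))
  expect_lt(rmse, 0.1 * stats::sd(d$Y))
})

test_that("classifier-based ratio matches the closed-form Gaussian oracle", {
  d <- gaussian_exposure_data(5000, seed = 5)
  spec <- shift_spec("a1", 0.5)
  rc <- fit_ratio_classifier(d, spec, roster = c("mean", "glm", "glm_twoway"),
                             seed = 1)
  one <- subset_rows(d, 1)
  for (a in c(0, 1)) {
    Ae <- matrix(a, 1, 1, dimnames = list(NULL, "a1"))
    est <- as.numeric(predict(rc, one, exposures = Ae))
    expect_lt(abs(est - gaussian_ratio_oracle(a, 0.5)), 0.05)
  }
  # importance-weight normalization: E[H] near 1
  expect_lt(abs(mean(predict(rc, d)) - 1), 0.03)
})

test_that("direct conditional-density ratio matches the Gaussian oracle", {
  d <- gaussian_exposure_data(5000, seed = 5)
  spec <- shift_spec("a1", 0.5)
  rd <- fit_conditional_density(d, spec, seed = 1)
  one <- subset_rows(d, 1)
  A0 <- matrix(0, 1, 1, dimnames = list(NULL, "a1"))
  expect_lt(abs(as.numeric(predict(rd, one, exposures = A0)) -
                  gaussian_ratio_oracle(0, 0.5)), 0.05)
  expect_lt(abs(mean(predict(rd, d)) - 1), 0.05)
  # zero shift: the direct ratio is exactly one everywhere
  rd0 <- fit_conditional_density(d, shift_spec("a1", 0), seed = 1)
  expect_equal(as.numeric(predict(rd0, d)), rep(1, d$n), tolerance = 1e-12)
  # degenerate residuals rejected
  dd <- d
  dd$A[, "a1"] <- 1
  expect_error(fit_conditional_density(dd, spec, roster = "mean"),
               "residual variance")
})

test_that("zero shift gives calibrated odds near one for the classifier", {
  d <- gaussian_exposure_data(2000, seed = 9)
  rc <- fit_ratio_classifier(d, shift_spec("a1", 0),
                             roster = c("mean", "glm"), seed = 1)
  h <- predict(rc, d)
  expect_lt(max(abs(h - 1)), 0.1)
})

test_that("joint clever covariate factorizes for independent exposures", {
  d <- gaussian_exposure_data(5000, seed = 11, p = 2)
  joint <- shift_spec(c("a1", "a2"), 0.5)
  rj <- fit_ratio_classifier(d, joint, roster = c("mean", "glm", "glm_twoway"),
                             seed = 1)
  h <- clever_covariate(rj, d, joint)
  oracle <- gaussian_ratio_oracle(d$A[, "a1"], 0.5) *
    gaussian_ratio_oracle(d$A[, "a2"], 0.5)
  # compare at interior points where the oracle is stable
  core <- abs(d$A[, "a1"]) < 1.5 & abs(d$A[, "a2"]) < 1.5
  expect_lt(max(abs(h[core] - oracle[core])), 0.05 * max(oracle[core]) + 0.05)
  # trained-spec consistency check
  expect_error(clever_covariate(rj, d, shift_spec("a1", 0.5)),
               "different shift")
})

test_that("ratio truncation respects floor and ceiling", {
  d <- gaussian_exposure_data(1000, seed = 3)
  rc <- fit_ratio_classifier(d, shift_spec("a1", 2),
                             roster = c("mean", "glm"), seed = 1,
                             ceiling = 1.5)
  h <- predict(rc, d)
  expect_lte(max(h), 1.5)
  expect_gte(min(h), 1e-6)
  # default ceiling caps extreme shifts at 50
  rc50 <- fit_ratio_classifier(d, shift_spec("a1", 5),
                               roster = c("mean", "glm", "glm_twoway"),
                               seed = 1)
  expect_lte(max(predict(rc50, d)), 50)
})
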