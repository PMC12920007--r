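# Simulation framework: a six-exposure data-generating mechanism with
# built-in synergy (A1, A2) and antagonism (A5, A6), truth computation for
# the shift interaction, a replicate runner, and performance metrics.

#' Define a simulation scenario
#'
#' The generated data have four exchangeably correlated Gaussian confounders
#' and six continuous exposures with right-skewed or bounded distributions
#' confounded by W, and outcome
#' \deqn{Y = 1 + 0.3 W_1 + 0.2 W_2 + 0.3 A_1 + 0.2 A_2 - 0.3 A_3 +
#'   \beta_s A_1 A_2 + \beta_a A_5 A_6 + 0.2 A_4^2 + \epsilon,}
#' with \eqn{\epsilon \sim N(0, 1)}, synergy strength \eqn{\beta_s} on the
#' (A1, A2) product and antagonism strength \eqn{\beta_a} on (A5, A6).
#'
#' @param n Sample size (>= 50).
#' @param synergy Synergy strength (typical grid 0.25, 0.40, 0.60).
#' @param antagonism Antagonism strength (typical grid -0.20, -0.45, -0.70).
#' @param rho Exchangeable correlation among the confounders.
#' @param delta Length-2 shift applied to (A1, A2) when estimating the
#'   built-in interaction (default +0.5 each).
#' @param replicates Number of replicates for [run_replicates()].
#' @param seed Master seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n, synergy = 0.25, antagonism = -0.20, rho = 0.3,
                         delta = c(0.5, 0.5), replicates = 100L,
                         seed = NULL) {
  stopifnot(n >= 50L, replicates >= 1L, rho > -1, rho < 1,
            length(delta) == 2L)
  structure(list(n = as.integer(n), synergy = synergy,
                 antagonism = antagonism, rho = rho, delta = delta,
                 replicates = as.integer(replicates), seed = seed),
            class = "sim_scenario")
}

# Conditional outcome mean of the generative model.
sim_outcome_mean <- function(A, W, synergy, antagonism) {
  1.0 + 0.3 * W[, 1] + 0.2 * W[, 2] +
    0.3 * A[, "A1"] + 0.2 * A[, "A2"] - 0.3 * A[, "A3"] +
    synergy * A[, "A1"] * A[, "A2"] +
    antagonism * A[, "A5"] * A[, "A6"] +
    0.2 * A[, "A4"]^2
}

rtruncnorm01 <- function(n, mean, sd, lo, hi) {
  # inverse-CDF sampling of a truncated normal
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

sim_covariates_exposures <- function(n, rho) {
  Sigma <- matrix(rho, 4, 4)
  diag(Sigma) <- 1
  W <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = Sigma)
  colnames(W) <- paste0("W", 1:4)
  A <- cbind(
    A1 = stats::rgamma(n, shape = 2, scale = exp(0.2 * W[, 1])),
    A2 = stats::rgamma(n, shape = 2, scale = exp(0.2 * W[, 2])),
    A3 = 4 * stats::rbeta(n, 2, 2) + 0.1 * W[, 3],
    A4 = rtruncnorm01(n, 2 + 0.2 * W[, 3], 1, 0, 6),
    A5 = rtruncnorm01(n, 2 + 0.2 * W[, 3], 1, 0, 6),
    A6 = rtruncnorm01(n, 2 + 0.2 * W[, 4], 1, 0, 6)
  )
  list(W = W, A = A)
}

#' Simulate one dataset from the scenario's generative model
#'
#' Exposure families: A1, A2 are Gamma(shape 2) with scale
#' \eqn{\exp(0.2 W_1)} and \eqn{\exp(0.2 W_2)} (right-skewed, confounded);
#' A3 is Beta(2, 2) rescaled to \[0, 4\] and shifted by \eqn{0.1 W_3}
#' (bounded); A4, A5 are Normal(\eqn{2 + 0.2 W_3}, 1) truncated to \[0, 6\]
#' and A6 is Normal(\eqn{2 + 0.2 W_4}, 1) truncated to \[0, 6\].
#'
#' @param scenario A `sim_scenario`.
#' @param seed Optional seed overriding the scenario's.
#' @return A `mixture_dataset`.
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(seed, {
    cx <- sim_covariates_exposures(scenario$n, scenario$rho)
    mu <- sim_outcome_mean(cx$A, cx$W, scenario$synergy,
                           scenario$antagonism)
    Y <- mu + stats::rnorm(scenario$n)
    df <- data.frame(cx$W, cx$A, Y = Y)
    mixture_dataset(df, covariates = colnames(cx$W),
                    exposures = colnames(cx$A), outcome = "Y")
  })
}

#' True interaction value for the built-in (A1, A2) synergy
#'
#' Returns both a large-sample Monte-Carlo evaluation (draws from the same
#' generative model, averaging outcomes — with fresh noise — under the
#' joint shift, each marginal shift, and no shift) and the closed form
#' \eqn{\beta_s \delta_1 \delta_2}, exact here because the outcome is linear
#' in \eqn{A_1 A_2} and every other term cancels in the double difference.
#'
#' @param scenario A `sim_scenario`.
#' @param n_mc Monte-Carlo sample size.
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `closed_form`, `mc`, `mc_se`.
#' @export
true_interaction <- function(scenario, n_mc = 1e5, seed = 1L) {
  d <- scenario$delta
  closed <- scenario$synergy * d[1] * d[2]
  mc <- with_seed(seed, {
    cx <- sim_covariates_exposures(n_mc, scenario$rho)
    shift_cols <- function(A, d1, d2) {
      A[, "A1"] <- A[, "A1"] + d1
      A[, "A2"] <- A[, "A2"] + d2
      A
    }
    draw_y <- function(A) {
      sim_outcome_mean(A, cx$W, scenario$synergy, scenario$antagonism) +
        stats::rnorm(n_mc)
    }
    contrast <- draw_y(shift_cols(cx$A, d[1], d[2])) -
      draw_y(shift_cols(cx$A, d[1], 0)) -
      draw_y(shift_cols(cx$A, 0, d[2])) +
      draw_y(cx$A)
    c(mean(contrast), stats::sd(contrast) / sqrt(n_mc))
  })
  list(closed_form = closed, mc = mc[1], mc_se = mc[2])
}

#' Run simulation replicates through the discovery-estimation pipeline
#'
#' Per replicate: simulate a dataset, run [run_discovery_estimation()],
#' record the pooled rank-1 synergy interaction estimate with its CI, and
#' whether the built-in (A1, A2) pair was the top-ranked synergy pair in a
#' strict majority of folds. Aggregates to bias, MSE, coverage, discovery
#' rate and scaled bias against [true_interaction()].
#'
#' @param scenario A `sim_scenario`.
#' @param config A `shift_config` for the estimator (its `seed` is ignored;
#'   per-replicate seeds are derived from the scenario seed).
#' @param truth Optional truth value; defaults to the closed form.
#' @return A `sim_report`: summary metrics plus per-replicate records.
#' @export
run_replicates <- function(scenario, config = shift_config(),
                           truth = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  cfg <- if (inherits(config, "shift_config")) config
  else do.call(shift_config, config)
  truth <- truth %||% true_interaction(scenario)$closed_form
  N <- scenario$replicates
  out <- vector("list", N)
  n_fail <- 0L
  for (r in seq_len(N)) {
    rep_seed <- child_seed(scenario$seed %||% 1L, r, 9L)
    out[[r]] <- tryCatch({
      dat <- simulate_dataset(scenario, seed = rep_seed)
      cfg$seed <- child_seed(rep_seed, 1L)
      cfg$delta <- stats::setNames(
        c(scenario$delta[1], scenario$delta[2], rep(scenario$delta[1], 4)),
        paste0("A", 1:6))
      res <- run_discovery_estimation(dat, cfg)
      top_pairs <- vapply(res$ranked, function(rk) {
        if (nrow(rk$synergy) >= 1L) {
          paste(rk$synergy$exposure_i[1], rk$synergy$exposure_j[1], sep = "*")
        } else ""
      }, character(1))
      discovered <- mean(top_pairs == "A1*A2") > 0.5
      pl <- res$pooled$synergy[["synergy1"]]
      if (is.null(pl)) stop("no pooled synergy estimate")
      est <- pl$interaction
      data.frame(replicate = r, psi = est$psi_int, se = est$se,
                 ci_lo = est$ci_lo, ci_hi = est$ci_hi,
                 covered = est$ci_lo <= truth & truth <= est$ci_hi,
                 discovered = discovered,
                 delta_bar = mean(pl$delta_bar))
    }, error = function(e) {
      n_fail <<- n_fail + 1L
      NULL
    })
    if (n_fail > 0.2 * N && r >= 5L) {
      stop("more than 20% of replicates failed; scenario aborted")
    }
  }
  recs <- do.call(rbind, out)
  if (is.null(recs) || nrow(recs) == 0L) stop("all replicates failed")
  bias <- mean(recs$psi) - truth
  # population-variance convention so that MSE = bias^2 + var holds exactly
  var_psi <- mean((recs$psi - mean(recs$psi))^2)
  structure(
    list(
      scenario = scenario, truth = truth,
      n_replicates = nrow(recs), n_failed = n_fail,
      bias = bias, abs_bias = abs(bias),
      var_psi = var_psi, mse = bias^2 + var_psi,
      coverage = mean(recs$covered),
      discovery_rate = mean(recs$discovered),
      scaled_bias = abs(bias) * sqrt(scenario$n),
      degenerate = nrow(recs) < 2L,
      records = recs
    ),
    class = "sim_report"
  )
}

#' @export
print.sim_report <- function(x, ...) {
  cat(sprintf(
    "sim_report: n = %d, synergy = %.2f, %d replicate(s)%s\n",
    x$scenario$n, x$scenario$synergy, x$n_replicates,
    if (x$degenerate) " [degenerate variance]" else ""))
  cat(sprintf(
    "  truth %.4f | abs bias %.4f | MSE %.4f | coverage %.2f | discovery %.2f | scaled bias %.3f\n",
    x$truth, x$abs_bias, x$mse, x$coverage, x$discovery_rate,
    x$scaled_bias))
  if (x$n_failed > 0) cat(sprintf("  %d failed replicate(s)\n", x$n_failed))
  invisible(x)
}

#' Synthetic seven-exposure fixture with known interaction structure
#'
#' Generates a dataset emulating a mixtures benchmark layout: seven
#' correlated exposures and one binary confounder, with two correlated
#' clusters (A1, A2, A3) and (A5, A6); A1, A2, A7 contribute positively to
#' the outcome, A4, A5 negatively, and A3, A6 are null but correlated with
#' their cluster members; the pairs (A1, A7) and (A2, A7) are supra-additive
#' and (A5, A7) is antagonistic. All coefficients are invented test
#' constants for this synthetic fixture — they are not taken from any
#' external benchmark key.
#'
#' @param seed Integer seed.
#' @param n Sample size.
#' @return A `mixture_dataset`.
#' @export
make_niehs_like_fixture <- function(seed = 1L, n = 500L) {
  with_seed(seed, {
    W <- stats::rbinom(n, 1, 0.5)
    z_c1 <- stats::rnorm(n)   # latent factor for cluster A1-A3
    z_c2 <- stats::rnorm(n)   # latent factor for cluster A5-A6
    lat <- function(zc, load) {
      load * zc + sqrt(1 - load^2) * stats::rnorm(n)
    }
    expo <- function(z) exp(0.6 * z + 0.2 * W)
    A <- cbind(
      A1 = expo(lat(z_c1, 0.85)), A2 = expo(lat(z_c1, 0.85)),
      A3 = expo(lat(z_c1, 0.85)), A4 = expo(stats::rnorm(n)),
      A5 = expo(lat(z_c2, 0.85)), A6 = expo(lat(z_c2, 0.85)),
      A7 = expo(stats::rnorm(n))
    )
    mu <- 1 + 0.5 * W +
      1.0 * A[, "A1"] + 0.8 * A[, "A2"] - 0.7 * A[, "A4"] -
      0.9 * A[, "A5"] + 0.6 * A[, "A7"] +
      1.0 * A[, "A1"] * A[, "A7"] + 0.8 * A[, "A2"] * A[, "A7"] -
      0.8 * A[, "A5"] * A[, "A7"]
    Y <- mu + stats::rnorm(n)
    df <- data.frame(W1 = W, A, Y = Y)
    mixture_dataset(df, covariates = "W1",
                    exposures = paste0("A", 1:7), outcome = "Y")
  })
}
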