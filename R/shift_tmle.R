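# TMLE for the shifted-mean parameter E_delta[Y] with EIF-based inference.
# The efficient influence function of the shifted mean is
#   D(O) = H_delta(A, W) (Y - Qbar(A, W)) + Qbar(A + delta, W) - E_delta[Y],
# with clever covariate H_delta(A, W) = g0(A - delta | W) / g0(A | W); the
# fluctuation step solves its empirical score equation.

new_shift_estimate <- function(psi, eif, inference, delta, n,
                               fold = NA_integer_, condition = "shift",
                               epsilon = NA_real_, converged = TRUE,
                               score = NA_real_, max_ratio = NA_real_) {
  structure(
    list(psi = psi, eif = eif, se = inference$se,
         ci_lo = inference$ci_lo, ci_hi = inference$ci_hi,
         p_value = inference$p_value, delta = delta, n = n, fold = fold,
         condition = condition, epsilon = epsilon, converged = converged,
         score = score, max_ratio = max_ratio),
    class = "shift_estimate"
  )
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("%s: psi = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n = %d\n",
              x$condition, x$psi, x$se, x$ci_lo, x$ci_hi, x$p_value, x$n))
  invisible(x)
}

#' Wald inference from an influence-function vector
#'
#' The standard error is \eqn{\sqrt{\widehat{Var}(D)/n}} from the empirical
#' variance of the (mean-zero) influence function; confidence limits are
#' \eqn{\hat\psi \pm z_{1-\alpha/2} \, SE} and the p-value is the two-sided
#' Wald test against zero.
#'
#' @param eif Numeric influence-function vector (empirical mean approximately
#'   zero after targeting).
#' @param psi Point estimate.
#' @param alpha Significance level (default 0.05, giving 95% intervals).
#' @return List with `se`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
eif_inference <- function(eif, psi, alpha = 0.05) {
  n <- length(eif)
  if (n < 2L) stop("need at least two observations for inference")
  se <- sqrt(stats::var(eif) / n)
  z <- stats::qnorm(1 - alpha / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(psi) / se) else as.numeric(psi == 0)
  list(se = se, ci_lo = psi - z * se, ci_hi = psi + z * se, p_value = p)
}

#' Baseline mean outcome with influence-function inference
#'
#' The no-shift reference \eqn{E[Y]}: the sample mean, with influence
#' function \eqn{Y_i - \bar y}.
#'
#' @param data A `mixture_dataset`.
#' @param fold Optional fold label for provenance.
#' @param alpha Significance level.
#' @return A `shift_estimate` with `condition = "baseline"`.
#' @export
baseline_mean <- function(data, fold = NA_integer_, alpha = 0.05) {
  stopifnot(inherits(data, "mixture_dataset"), data$n >= 2L)
  psi <- mean(data$Y)
  eif <- data$Y - psi
  new_shift_estimate(psi, eif, eif_inference(eif, psi, alpha),
                     delta = 0, n = data$n, fold = fold,
                     condition = "baseline")
}

# One fluctuation pass. Returns updated unit-scale predictions at the
# observed and shifted exposures plus epsilon.
fluctuate <- function(y_unit, Q_obs_u, Q_shift_u, H_obs, H_shift,
                      fluctuation) {
  if (fluctuation == "logistic") {
    off <- logit(Q_obs_u)
    fit <- suppressWarnings(
      stats::glm.fit(matrix(H_obs, ncol = 1), y_unit,
                     family = stats::quasibinomial(), offset = off,
                     control = list(maxit = 100))
    )
    eps <- unname(fit$coefficients[1])
    if (!is.finite(eps)) eps <- 0
    list(eps = eps,
         Q_obs_u = bound(expit(logit(Q_obs_u) + eps * H_obs), 0, 1),
         Q_shift_u = bound(expit(logit(Q_shift_u) + eps * H_shift), 0, 1))
  } else {
    eps <- sum(H_obs * (y_unit - Q_obs_u)) / sum(H_obs^2)
    list(eps = eps,
         Q_obs_u = Q_obs_u + eps * H_obs,
         Q_shift_u = Q_shift_u + eps * H_shift)
  }
}

#' TMLE of the shifted-mean parameter
#'
#' Targeted maximum likelihood estimation of \eqn{E_\delta[Y]}, the mean
#' outcome under the stochastic shift `spec`. The initial outcome regression
#' is fluctuated along a one-dimensional submodel with the clever covariate
#' \eqn{H_\delta}: on the unit-rescaled outcome, a logistic submodel with
#' \eqn{H_\delta} as covariate and no intercept (default), or a linear
#' submodel \eqn{\bar Q^* = \bar Q + \epsilon H}. The estimate is the mean of
#' the updated regression at the post-intervention exposures
#' \eqn{A + \delta}, and inference comes from the empirical EIF.
#'
#' Nuisance models may have been fitted on held-out data (CV-TMLE); the
#' fluctuation always uses the rows of `data`.
#'
#' @param data A `mixture_dataset` (estimation rows).
#' @param spec A `shift_spec`.
#' @param Q An `outcome_model`.
#' @param g A `ratio_model` trained for `spec`.
#' @param fluctuation `"logistic"` (default) or `"linear"`.
#' @param fold,condition Provenance labels.
#' @param alpha Significance level.
#' @return A `shift_estimate`.
#' @export
tmle_shift_mean <- function(data, spec, Q, g,
                            fluctuation = c("logistic", "linear"),
                            fold = NA_integer_, condition = NULL,
                            alpha = 0.05) {
  fluctuation <- match.arg(fluctuation)
  check_spec(data, spec)
  A_shift <- apply_shift(data, spec, mode = "post-intervention")
  H_obs <- clever_covariate(g, data, spec)
  max_ratio <- attr(H_obs, "max_ratio")
  H_obs <- as.numeric(H_obs)
  H_shift <- as.numeric(predict(g, data, exposures = A_shift))
  parts <- tmle_shift_parts(data, A_shift, H_obs, H_shift, Q, fluctuation)
  condition <- condition %||%
    paste(sprintf("%s%+g", spec$targets, spec$delta), collapse = " & ")
  new_shift_estimate(
    parts$psi, parts$eif, eif_inference(parts$eif, parts$psi, alpha),
    delta = spec$delta, n = data$n, fold = fold, condition = condition,
    epsilon = parts$eps, converged = abs(parts$eps) <= 10,
    score = parts$score, max_ratio = max_ratio
  )
}

# Shared fluctuation/plug-in/EIF computation, reused by the pooled CV-TMLE
# where nuisance predictions come stacked from different folds.
tmle_shift_parts <- function(data, A_shift, H_obs, H_shift, Q, fluctuation) {
  y_u <- to_unit(Q, data$Y)
  Q_obs_u <- predict(Q, data, scale = "unit")
  Q_shift_u <- predict(Q, data, exposures = A_shift, scale = "unit")
  tmle_shift_parts_stacked(data$Y, y_u, Q_obs_u, Q_shift_u, H_obs, H_shift,
                           Q$y_lo, Q$y_hi, fluctuation)
}

tmle_shift_parts_stacked <- function(Y, y_u, Q_obs_u, Q_shift_u, H_obs,
                                     H_shift, y_lo, y_hi, fluctuation) {
  fl <- fluctuate(y_u, Q_obs_u, Q_shift_u, H_obs, H_shift, fluctuation)
  scale <- y_hi - y_lo
  Q_obs_n <- y_lo + scale * fl$Q_obs_u
  Q_shift_n <- y_lo + scale * fl$Q_shift_u
  psi <- mean(Q_shift_n)
  eif <- as.numeric(H_obs) * (Y - Q_obs_n) + Q_shift_n - psi
  score <- mean(H_obs * (y_u - fl$Q_obs_u))
  if (abs(fl$eps) > 10) {
    warning("fluctuation coefficient |epsilon| > 10; estimate flagged")
  }
  list(psi = psi, eif = eif, eps = fl$eps, score = score)
}
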