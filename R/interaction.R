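# The two-way additive interaction parameter
#   Psi_int = E_delta[Y] - E_delta_i[Y] - E_delta_j[Y] + E[Y],
# the departure of the joint-shift mean from additivity of the two marginal
# shifts. Positive values indicate synergy (super-additivity), negative
# values antagonism. Estimated either by combining four separately targeted
# shifted means (delta method) or by a single targeting pass with a combined
# clever covariate.

new_interaction_estimate <- function(psi_int, eif, inference, approach, pair,
                                     deltas, n, fold = NA_integer_,
                                     components = NULL, epsilon = NA_real_,
                                     converged = TRUE, score = NA_real_) {
  structure(
    list(psi_int = psi_int, eif = eif, se = inference$se,
         ci_lo = inference$ci_lo, ci_hi = inference$ci_hi,
         p_value = inference$p_value, approach = approach, pair = pair,
         deltas = deltas, n = n, fold = fold, components = components,
         epsilon = epsilon, converged = converged, score = score),
    class = "interaction_estimate"
  )
}

#' @export
print.interaction_estimate <- function(x, ...) {
  cat(sprintf(
    "interaction (%s) %s & %s: psi = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
    x$approach, x$pair[1], x$pair[2], x$psi_int, x$se, x$ci_lo, x$ci_hi,
    x$p_value))
  invisible(x)
}

#' Interaction estimate from four targeted components (delta method)
#'
#' Combines separately targeted estimates of the joint-shift mean, the two
#' marginal-shift means and the baseline mean into
#' \eqn{\hat\Psi_{int} = \hat\psi_{\delta} - \hat\psi_{\delta_i} -
#' \hat\psi_{\delta_j} + \hat\psi_0}. The variance accounts for the
#' covariance among components through the combined influence function
#' \eqn{D = D_\delta - D_{\delta_i} - D_{\delta_j} + D_0}, with
#' \eqn{D_{0,i} = Y_i - \bar y}.
#'
#' @param joint,marg_i,marg_j,baseline `shift_estimate`s computed on the same
#'   rows (aligned EIF vectors).
#' @param pair Character pair of exposure names (provenance).
#' @param alpha Significance level.
#' @return An `interaction_estimate` with `approach = "delta"`.
#' @export
interaction_delta_method <- function(joint, marg_i, marg_j, baseline,
                                     pair = c("i", "j"), alpha = 0.05) {
  ns <- c(length(joint$eif), length(marg_i$eif), length(marg_j$eif),
          length(baseline$eif))
  if (length(unique(ns)) != 1L) stop("misaligned EIF lengths")
  psi_int <- joint$psi - marg_i$psi - marg_j$psi + baseline$psi
  eif <- joint$eif - marg_i$eif - marg_j$eif + baseline$eif
  new_interaction_estimate(
    psi_int, eif, eif_inference(eif, psi_int, alpha),
    approach = "delta", pair = pair,
    deltas = joint$delta, n = ns[1], fold = joint$fold,
    components = list(joint = joint, marg_i = marg_i, marg_j = marg_j,
                      baseline = baseline)
  )
}

#' Combined clever covariate for direct interaction targeting
#'
#' Elementwise \eqn{H^* = H_{\delta} - H_{\delta_i} - H_{\delta_j} + 1},
#' where the three ratio vectors come from the joint and the two marginal
#' shift specifications; the `+1` is the (constant) clever covariate of the
#' baseline mean.
#'
#' @param h_joint,h_i,h_j Numeric ratio vectors of equal length.
#' @return Numeric vector \eqn{H^*}.
#' @export
combined_clever_covariate <- function(h_joint, h_i, h_j) {
  if (length(h_i) != length(h_joint) || length(h_j) != length(h_joint)) {
    stop("length mismatch among ratio vectors")
  }
  as.numeric(h_joint) - as.numeric(h_i) - as.numeric(h_j) + 1
}

# The four exposure configurations entering the interaction contrast.
interaction_configs <- function(data, spec_joint, spec_i, spec_j) {
  list(
    joint = apply_shift(data, spec_joint, mode = "post-intervention"),
    i = apply_shift(data, spec_i, mode = "post-intervention"),
    j = apply_shift(data, spec_j, mode = "post-intervention"),
    obs = data$A
  )
}

make_pair_specs <- function(pair, deltas) {
  list(
    joint = shift_spec(pair, deltas),
    i = shift_spec(pair[1], deltas[1]),
    j = shift_spec(pair[2], deltas[2])
  )
}

# H*(a) evaluated at an arbitrary exposure configuration.
hstar_at <- function(ratios, data, A_eval) {
  combined_clever_covariate(
    predict(ratios$joint, data, exposures = A_eval),
    predict(ratios$i, data, exposures = A_eval),
    predict(ratios$j, data, exposures = A_eval)
  )
}

#' Single-step TMLE of the interaction parameter (direct targeting)
#'
#' Targets \eqn{\Psi_{int}} in one fluctuation pass: the initial outcome
#' regression is updated along a submodel with the combined clever covariate
#' \eqn{H^*}, making the empirical mean of the interaction EIF zero. The
#' updated regression is then evaluated at the four exposure configurations
#' (joint shift, each marginal shift, observed) and averaged into the
#' plug-in contrast. The EIF is
#' \eqn{H^*(Y - \bar Q^*) + [\bar Q^*(joint) - \bar Q^*(i) - \bar Q^*(j) +
#' \bar Q^*(obs)] - \Psi_{int}}.
#'
#' @param data A `mixture_dataset` (estimation rows).
#' @param pair Character vector of the two exposure names.
#' @param deltas Numeric length-2 shifts for the pair.
#' @param Q An `outcome_model`.
#' @param ratios List of three `ratio_model`s named `joint`, `i`, `j`
#'   (trained for the joint and marginal specifications; see
#'   [fit_pair_ratios()]).
#' @param fluctuation `"logistic"` or `"linear"`.
#' @param fold Provenance label.
#' @param alpha Significance level.
#' @return An `interaction_estimate` with `approach = "direct"`.
#' @export
tmle_interaction_direct <- function(data, pair, deltas, Q, ratios,
                                    fluctuation = c("logistic", "linear"),
                                    fold = NA_integer_, alpha = 0.05) {
  fluctuation <- match.arg(fluctuation)
  stopifnot(length(pair) == 2L, length(deltas) == 2L)
  specs <- make_pair_specs(pair, deltas)
  configs <- interaction_configs(data, specs$joint, specs$i, specs$j)
  Hs <- lapply(configs, function(A_eval) hstar_at(ratios, data, A_eval))
  Qu <- lapply(configs, function(A_eval)
    predict(Q, data, exposures = A_eval, scale = "unit"))
  y_u <- to_unit(Q, data$Y)

  if (all(abs(Hs$obs) < .Machine$double.eps^0.5)) {
    eps <- 0  # degenerate covariate (e.g. zero shifts): nothing to target
  } else if (fluctuation == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(matrix(Hs$obs, ncol = 1), y_u,
                     family = stats::quasibinomial(), offset = logit(Qu$obs),
                     control = list(maxit = 100))
    )
    eps <- unname(fit$coefficients[1])
    if (!is.finite(eps)) eps <- 0
  } else {
    eps <- sum(Hs$obs * (y_u - Qu$obs)) / sum(Hs$obs^2)
  }
  update <- function(qu, h) {
    if (fluctuation == "logistic") bound(expit(logit(qu) + eps * h), 0, 1)
    else qu + eps * h
  }
  Qn <- Map(function(qu, h) from_unit(Q, update(qu, h)), Qu, Hs)
  contrast <- Qn$joint - Qn$i - Qn$j + Qn$obs
  psi_int <- mean(contrast)
  eif <- Hs$obs * (data$Y - Qn$obs) + contrast - psi_int
  score <- mean(Hs$obs * (y_u - update(Qu$obs, Hs$obs)))
  if (abs(eps) > 10) {
    warning("fluctuation coefficient |epsilon| > 10; estimate flagged")
  }
  new_interaction_estimate(
    psi_int, eif, eif_inference(eif, psi_int, alpha),
    approach = "direct", pair = pair, deltas = deltas, n = data$n,
    fold = fold, epsilon = eps, converged = abs(eps) <= 10, score = score
  )
}

#' Fit the three density-ratio models needed for a pair
#'
#' Joint ratios are learned by a single model on the jointly shifted copies
#' (not as a product of marginals), respecting dependence between the
#' exposures.
#'
#' @inheritParams tmle_interaction_direct
#' @param train Training `mixture_dataset` for the ratio fits.
#' @param method,roster,V,seed,ceiling Passed to [fit_ratio()].
#' @return List of `ratio_model`s named `joint`, `i`, `j`.
#' @export
fit_pair_ratios <- function(train, pair, deltas,
                            method = c("classifier", "direct"),
                            roster = NULL, V = 5L, seed = NULL,
                            ceiling = .RATIO_CEILING) {
  method <- match.arg(method)
  specs <- make_pair_specs(pair, deltas)
  list(
    joint = fit_ratio(train, specs$joint, method, roster, V,
                      child_seed(seed, 1L), ceiling),
    i = fit_ratio(train, specs$i, method, roster, V,
                  child_seed(seed, 2L), ceiling),
    j = fit_ratio(train, specs$j, method, roster, V,
                  child_seed(seed, 3L), ceiling)
  )
}

#' G-computation interaction contrast (no targeting)
#'
#' The plug-in double difference
#' \eqn{\frac{1}{n}\sum_i [\bar Q(A_i + \delta_{ij}, W_i) -
#' \bar Q(A_i + \delta_i, W_i) - \bar Q(A_i + \delta_j, W_i) +
#' \bar Q(A_i, W_i)]} under the fitted (untargeted) outcome regression; used
#' for fast pair ranking in the discovery stage. No standard error is
#' attached — inference for discovered pairs comes from the TMLE stage.
#'
#' @param Q An `outcome_model` fitted on the same training fold.
#' @param data A `mixture_dataset`.
#' @param pair Character vector of two exposure names.
#' @param deltas Numeric length-2 shifts.
#' @return A single numeric value.
#' @export
gcomp_interaction <- function(Q, data, pair, deltas) {
  stopifnot(length(pair) == 2L, length(deltas) == 2L)
  specs <- make_pair_specs(pair, deltas)
  configs <- interaction_configs(data, specs$joint, specs$i, specs$j)
  preds <- lapply(configs, function(A_eval)
    predict(Q, data, exposures = A_eval, scale = "natural"))
  mean(preds$joint - preds$i - preds$j + preds$obs)
}

#' G-computation contrast for a single shift
#'
#' Plug-in mean difference \eqn{\frac{1}{n}\sum_i [\bar Q(A_i + \delta, W_i)
#' - \bar Q(A_i, W_i)]}; used to rank single exposures by shift response.
#'
#' @inheritParams gcomp_interaction
#' @param spec A `shift_spec`.
#' @return A single numeric value.
#' @export
gcomp_shift <- function(Q, data, spec) {
  A_shift <- apply_shift(data, spec, mode = "post-intervention")
  mean(predict(Q, data, exposures = A_shift, scale = "natural") -
         predict(Q, data, scale = "natural"))
}

#' Three-way g-computation interaction contrast
#'
#' The third-order finite difference over the eight shift configurations of
#' three exposures:
#' \eqn{E_{ijk} - (E_{ij} + E_{ik} + E_{jk}) + (E_i + E_j + E_k) - E_0},
#' each term the plug-in mean of \eqn{\bar Q} at the corresponding
#' post-intervention exposures. Purely additive or pairwise-only response
#' surfaces give exactly zero; a pure triple product
#' \eqn{\gamma a_i a_j a_k} gives \eqn{\gamma \delta_i \delta_j \delta_k}.
#'
#' @inheritParams gcomp_interaction
#' @param triple Character vector of three exposure names.
#' @param deltas Numeric length-3 shifts.
#' @return A single numeric value.
#' @export
gcomp_threeway <- function(Q, data, triple, deltas) {
  stopifnot(length(triple) == 3L, length(deltas) == 3L)
  total <- 0
  for (mask in 0:7) {
    on <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    k <- sum(on)
    A_eval <- if (k == 0L) data$A else
      apply_shift(data, shift_spec(triple[on], deltas[on]),
                  mode = "post-intervention")
    sign <- (-1)^(3 - k)
    total <- total +
      sign * mean(predict(Q, data, exposures = A_eval, scale = "natural"))
  }
  total
}
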