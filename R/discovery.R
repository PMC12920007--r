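# K-fold discovery-estimation: rank exposure pairs by g-computation on
# training folds, estimate the top-ranked pairs by TMLE on validation folds,
# adapt shift magnitudes to respect positivity, and pool fold estimates
# through a single targeting step over the stacked validation predictions.

#' Build a cross-validation fold plan
#'
#' Validation folds are pairwise disjoint, cover `1..n`, and differ in size
#' by at most one; each training set is the complement of its validation
#' set. Deterministic given `seed`.
#'
#' @param n Number of observations.
#' @param K Number of folds, `2 <= K <= n`.
#' @param seed Optional integer seed.
#' @return A `fold_plan`: list with `K`, `seed` and per-fold `train`/`valid`
#'   index vectors.
#' @export
make_folds <- function(n, K, seed = NULL) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2: discovery requires a held-out fold")
  if (K > n) stop("K may not exceed n")
  labels <- with_seed(seed, sample(rep_len(seq_len(K), n)))
  folds <- lapply(seq_len(K), function(k) {
    v <- which(labels == k)
    list(train = which(labels != k), valid = v)
  })
  structure(list(K = K, seed = seed, folds = folds), class = "fold_plan")
}

#' Rank exposure pairs by g-computation interaction on a training fold
#'
#' Evaluates [gcomp_interaction()] for every unordered exposure pair, breaks
#' ties lexicographically by pair name, and returns the top-`s` synergy set
#' (largest strictly positive contrasts, descending) and top-`s` antagonism
#' set (most negative, ascending). A pair enters the synergy set only when
#' its contrast is positive, and the antagonism set only when negative.
#'
#' @param train Training `mixture_dataset`.
#' @param Q An `outcome_model` fitted on `train`.
#' @param deltas Named numeric vector of shifts per exposure (or a scalar
#'   applied to all exposures).
#' @param s Number of pairs to retain per sign.
#' @return A `ranked_pairs` object: full pair table plus `synergy` and
#'   `antagonism` data.frames.
#' @export
rank_pairs <- function(train, Q, deltas, s = 1L) {
  exp_names <- train$exposures
  if (length(exp_names) < 2L) stop("need at least two exposures")
  deltas <- expand_delta_map(deltas, exp_names)
  pairs <- utils::combn(exp_names, 2L)
  vals <- apply(pairs, 2L, function(pr)
    gcomp_interaction(Q, train, pr, deltas[pr]))
  tab <- data.frame(
    exposure_i = pairs[1L, ], exposure_j = pairs[2L, ],
    value = vals, stringsAsFactors = FALSE
  )
  pair_name <- paste(tab$exposure_i, tab$exposure_j, sep = "*")
  # sign rule with a scale-aware zero: float residue from an additive fit
  # (contrasts ~ 1e-15) must not qualify as synergy or antagonism
  tol0 <- 1e-8 * max(stats::sd(train$Y), .Machine$double.eps)
  syn <- tab[order(-tab$value, pair_name), , drop = FALSE]
  syn <- syn[syn$value > tol0, , drop = FALSE]
  syn <- utils::head(syn, s)
  if (nrow(syn)) syn$rank <- seq_len(nrow(syn))
  ant <- tab[order(tab$value, pair_name), , drop = FALSE]
  ant <- ant[ant$value < -tol0, , drop = FALSE]
  ant <- utils::head(ant, s)
  if (nrow(ant)) ant$rank <- seq_len(nrow(ant))
  structure(list(table = tab, synergy = syn, antagonism = ant,
                 deltas = deltas, s = s),
            class = "ranked_pairs")
}

expand_delta_map <- function(deltas, exp_names) {
  if (length(deltas) == 1L && is.null(names(deltas))) {
    deltas <- stats::setNames(rep(as.numeric(deltas), length(exp_names)),
                              exp_names)
  }
  missing_d <- setdiff(exp_names, names(deltas))
  if (length(missing_d) > 0L) {
    stop("no delta declared for exposure(s): ",
         paste(missing_d, collapse = ", "))
  }
  deltas[exp_names]
}

#' Shrink a shift until the density ratio respects the positivity ceiling
#'
#' Starting from the requested shift, multiplies its magnitude by `shrink`
#' (default 0.9) until the maximum pre-truncation density ratio over the
#' training rows falls below the ceiling \eqn{\lambda}, refitting the ratio
#' model at each candidate. Ratios below 1 pose no positivity risk, so no
#' lower bound is enforced. Fails once the magnitude drops below
#' `floor_frac` of the initial request.
#'
#' @param train Training `mixture_dataset`.
#' @param spec Requested `shift_spec` (all targets are shrunk jointly).
#' @param ratio_factory Function `(spec) -> ratio_model` fitted on `train`.
#' @param lambda Ratio ceiling, `> 1`.
#' @param shrink Multiplicative step on a grid, in (0, 1).
#' @param floor_frac Minimum fraction of the initial magnitude.
#' @return List with the adapted `spec`, the fitted `model` at that shift,
#'   `max_ratio`, and `n_shrink` (number of grid steps taken).
#' @export
adapt_delta <- function(train, spec, ratio_factory, lambda = .RATIO_CEILING,
                        shrink = 0.9, floor_frac = 0.01) {
  stopifnot(lambda > 1, shrink > 0, shrink < 1)
  delta0 <- spec$delta
  frac <- 1
  n_shrink <- 0L
  repeat {
    cand <- shift_spec(spec$targets, delta0 * frac)
    model <- ratio_factory(cand)
    h <- predict(model, train)
    max_ratio <- attr(h, "max_ratio")
    if (max_ratio < lambda) {
      return(list(spec = cand, model = model, max_ratio = max_ratio,
                  n_shrink = n_shrink))
    }
    frac <- frac * shrink
    n_shrink <- n_shrink + 1L
    if (frac < floor_frac) {
      stop("positivity: ratio ceiling unattainable at ", floor_frac,
           " of the requested shift")
    }
  }
}

#' Track how often each pair is discovered across folds
#'
#' @param ranked_list List of `ranked_pairs`, one per fold.
#' @param which_set `"synergy"` or `"antagonism"`.
#' @return Data.frame with one row per pair ever discovered: fold count,
#'   mean rank where present, and a `robust` flag (present in more than half
#'   the folds).
#' @export
rank_consistency <- function(ranked_list, which_set = c("synergy",
                                                        "antagonism")) {
  which_set <- match.arg(which_set)
  K <- length(ranked_list)
  if (K < 2L) stop("need at least two folds")
  rows <- do.call(rbind, lapply(ranked_list, function(r) r[[which_set]]))
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(exposure_i = character(), exposure_j = character(),
                      frequency = integer(), mean_rank = numeric(),
                      robust = logical()))
  }
  key <- paste(rows$exposure_i, rows$exposure_j, sep = "*")
  agg <- lapply(split(rows, key), function(d) {
    data.frame(exposure_i = d$exposure_i[1], exposure_j = d$exposure_j[1],
               frequency = nrow(d), mean_rank = mean(d$rank))
  })
  out <- do.call(rbind, agg)
  out$robust <- out$frequency > K / 2
  out <- out[order(-out$frequency, out$mean_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Configuration for a discovery-estimation run
#'
#' @param K Number of cross-validation folds (>= 2).
#' @param s Pairs retained per sign in discovery.
#' @param delta Scalar shift applied to every exposure, or a named vector.
#' @param lambda Positivity ceiling for density ratios.
#' @param approach `"delta"` (combine four targeted components) or
#'   `"direct"` (single-pass interaction TMLE).
#' @param density_method `"classifier"` or `"direct"` ratio estimation.
#' @param fluctuation `"logistic"` or `"linear"` submodel.
#' @param q_roster,g_roster Learner rosters for the outcome regression and
#'   the ratio model.
#' @param V Inner CV folds for learner selection.
#' @param seed Master seed; per-fold streams are derived from it.
#' @param pool_by `"rank"` (default; pairs aligned by discovery rank, as
#'   pair identity may change across folds) or `"pair"` (pool only folds
#'   that discovered the modal pair).
#' @param marginals Also rank and estimate the top positive / top negative
#'   single-exposure shifts.
#' @param alpha Significance level.
#' @return A `shift_config` list.
#' @export
shift_config <- function(K = 3L, s = 1L, delta = 1, lambda = .RATIO_CEILING,
                         approach = c("delta", "direct"),
                         density_method = c("classifier", "direct"),
                         fluctuation = c("logistic", "linear"),
                         q_roster = default_roster(),
                         g_roster = default_roster(),
                         V = 5L, seed = NULL,
                         pool_by = c("rank", "pair"),
                         marginals = TRUE, alpha = 0.05) {
  cfg <- list(
    K = as.integer(K), s = as.integer(s), delta = delta, lambda = lambda,
    approach = match.arg(approach),
    density_method = match.arg(density_method),
    fluctuation = match.arg(fluctuation),
    q_roster = q_roster, g_roster = g_roster, V = as.integer(V),
    seed = seed, pool_by = match.arg(pool_by),
    marginals = isTRUE(marginals), alpha = alpha
  )
  if (cfg$K < 2L) stop("K must be at least 2: discovery requires a held-out fold")
  if (cfg$s < 1L) stop("s must be at least 1")
  if (cfg$lambda <= 1) stop("lambda must exceed 1")
  structure(cfg, class = "shift_config")
}

# --- internal: one discovered pair estimated on a validation fold ----------

# Carries everything pooling needs: natural-scale outcome predictions and
# clever covariates at each configuration, for this fold's validation rows.
estimate_pair_fold <- function(valid, pair, deltas, Q, ratios, cfg, k) {
  specs <- make_pair_specs(pair, deltas)
  configs <- interaction_configs(valid, specs$joint, specs$i, specs$j)
  base <- baseline_mean(valid, fold = k, alpha = cfg$alpha)
  marg_i <- tmle_shift_mean(valid, specs$i, Q, ratios$i, cfg$fluctuation,
                            fold = k, alpha = cfg$alpha)
  marg_j <- tmle_shift_mean(valid, specs$j, Q, ratios$j, cfg$fluctuation,
                            fold = k, alpha = cfg$alpha)
  joint <- tmle_shift_mean(valid, specs$joint, Q, ratios$joint,
                           cfg$fluctuation, fold = k, alpha = cfg$alpha)
  inter <- if (cfg$approach == "delta") {
    interaction_delta_method(joint, marg_i, marg_j, base, pair = pair,
                             alpha = cfg$alpha)
  } else {
    tmle_interaction_direct(valid, pair, deltas, Q, ratios,
                            fluctuation = cfg$fluctuation, fold = k,
                            alpha = cfg$alpha)
  }
  inter$fold <- k
  stack <- list(
    Y = valid$Y,
    Q_nat = lapply(configs, function(A_eval)
      predict(Q, valid, exposures = A_eval, scale = "natural")),
    H_joint = lapply(configs, function(A_eval)
      as.numeric(predict(ratios$joint, valid, exposures = A_eval))),
    H_i = lapply(configs, function(A_eval)
      as.numeric(predict(ratios$i, valid, exposures = A_eval))),
    H_j = lapply(configs, function(A_eval)
      as.numeric(predict(ratios$j, valid, exposures = A_eval)))
  )
  list(pair = pair, deltas = deltas, fold = k,
       baseline = base, marg_i = marg_i, marg_j = marg_j, joint = joint,
       interaction = inter, stack = stack)
}

estimate_marginal_fold <- function(valid, exposure, delta, Q, model, cfg, k) {
  spec <- shift_spec(exposure, delta)
  A_shift <- apply_shift(valid, spec, mode = "post-intervention")
  est <- tmle_shift_mean(valid, spec, Q, model, cfg$fluctuation, fold = k,
                         alpha = cfg$alpha)
  stack <- list(
    Y = valid$Y,
    Q_obs = predict(Q, valid, scale = "natural"),
    Q_shift = predict(Q, valid, exposures = A_shift, scale = "natural"),
    H_obs = as.numeric(predict(model, valid)),
    H_shift = as.numeric(predict(model, valid, exposures = A_shift))
  )
  list(exposure = exposure, delta = unname(spec$delta), fold = k,
       estimate = est, baseline = baseline_mean(valid, fold = k),
       stack = stack)
}

# --- pooled (stacked) targeting --------------------------------------------

global_bounds <- function(Y) {
  m <- 0.1 * diff(range(Y))
  if (m == 0) m <- 0.1
  c(min(Y) - m, max(Y) + m)
}

unitize <- function(x, b) bound((x - b[1]) / (b[2] - b[1]),
                                .QBOUNDS[1], .QBOUNDS[2])

# Pooled single-shift TMLE: one fluctuation over stacked validation rows,
# each row carrying its own fold's nuisance predictions.
pool_shift <- function(stacks, condition, delta_bar, fluctuation, alpha) {
  Y <- unlist(lapply(stacks, `[[`, "Y"))
  b <- global_bounds(Y)
  parts <- tmle_shift_parts_stacked(
    Y, bound((Y - b[1]) / (b[2] - b[1]), 0, 1),
    unitize(unlist(lapply(stacks, `[[`, "Q_obs")), b),
    unitize(unlist(lapply(stacks, `[[`, "Q_shift")), b),
    unlist(lapply(stacks, `[[`, "H_obs")),
    unlist(lapply(stacks, `[[`, "H_shift")),
    b[1], b[2], fluctuation
  )
  new_shift_estimate(parts$psi, parts$eif,
                     eif_inference(parts$eif, parts$psi, alpha),
                     delta = delta_bar, n = length(Y), fold = NA_integer_,
                     condition = condition, epsilon = parts$eps,
                     converged = abs(parts$eps) <= 10, score = parts$score)
}

# Pooled direct-targeting interaction over stacked validation rows.
pool_interaction_direct <- function(stacks, pair_label, delta_bar,
                                    fluctuation, alpha) {
  Y <- unlist(lapply(stacks, `[[`, "Y"))
  b <- global_bounds(Y)
  cfgs <- c("joint", "i", "j", "obs")
  Qu <- lapply(cfgs, function(cc)
    unitize(unlist(lapply(stacks, function(s) s$Q_nat[[cc]])), b))
  names(Qu) <- cfgs
  Hs <- lapply(cfgs, function(cc) {
    combined_clever_covariate(
      unlist(lapply(stacks, function(s) s$H_joint[[cc]])),
      unlist(lapply(stacks, function(s) s$H_i[[cc]])),
      unlist(lapply(stacks, function(s) s$H_j[[cc]]))
    )
  })
  names(Hs) <- cfgs
  y_u <- bound((Y - b[1]) / (b[2] - b[1]), 0, 1)
  if (all(abs(Hs$obs) < .Machine$double.eps^0.5)) {
    eps <- 0
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
  Qn <- Map(function(qu, h) b[1] + (b[2] - b[1]) * update(qu, h), Qu, Hs)
  contrast <- Qn$joint - Qn$i - Qn$j + Qn$obs
  psi_int <- mean(contrast)
  eif <- Hs$obs * (Y - Qn$obs) + contrast - psi_int
  new_interaction_estimate(
    psi_int, eif, eif_inference(eif, psi_int, alpha),
    approach = "direct", pair = pair_label, deltas = delta_bar,
    n = length(Y), epsilon = eps, converged = abs(eps) <= 10,
    score = mean(Hs$obs * (y_u - update(Qu$obs, Hs$obs)))
  )
}

#' Pool fold-specific pair estimates into a single targeted estimate
#'
#' Pooling is by discovery rank: the pair identity may change across folds,
#' so the pooled rows describe the rank-1 (rank-r) discovery, with the
#' per-fold pair names recorded as provenance. One fluctuation is run on the
#' stacked validation rows — each row using its own fold's nuisance
#' predictions and clever covariates — followed by the stacked plug-in mean;
#' the standard error comes from the stacked EIF over all n. The reported
#' shift is the average \eqn{\bar\delta} of the fold-specific (possibly
#' adapted) shifts.
#'
#' @param fold_records List over folds of pair-estimation records (as built
#'   by [run_discovery_estimation()]).
#' @param cfg A `shift_config`.
#' @return List with pooled `shift_estimate`s (`marg_i`, `marg_j`, `joint`,
#'   `baseline`), the pooled `interaction` estimate, `delta_bar`, and the
#'   per-fold pair provenance.
#' @export
pool_folds <- function(fold_records, cfg) {
  if (length(fold_records) < 1L) stop("no fold records to pool")
  ok <- !vapply(fold_records, is.null, logical(1))
  if (!all(ok)) stop("missing rank in a fold: cannot pool")
  stacks <- lapply(fold_records, `[[`, "stack")
  deltas_k <- do.call(rbind, lapply(fold_records, `[[`, "deltas"))
  delta_bar <- colMeans(deltas_k)
  pairs_k <- do.call(rbind, lapply(fold_records, `[[`, "pair"))
  var1 <- paste(unique(pairs_k[, 1]), collapse = "/")
  var2 <- paste(unique(pairs_k[, 2]), collapse = "/")

  shift_stack <- function(cc, h_field) {
    lapply(stacks, function(s) list(
      Y = s$Y, Q_obs = s$Q_nat$obs, Q_shift = s$Q_nat[[cc]],
      H_obs = s[[h_field]]$obs, H_shift = s[[h_field]][[cc]]
    ))
  }
  marg_i <- pool_shift(shift_stack("i", "H_i"), paste("Var 1:", var1),
                       delta_bar[1], cfg$fluctuation, cfg$alpha)
  marg_j <- pool_shift(shift_stack("j", "H_j"), paste("Var 2:", var2),
                       delta_bar[2], cfg$fluctuation, cfg$alpha)
  joint <- pool_shift(shift_stack("joint", "H_joint"), "Joint",
                      mean(delta_bar), cfg$fluctuation, cfg$alpha)
  Y_all <- unlist(lapply(stacks, `[[`, "Y"))
  mu <- mean(Y_all)
  base_eif <- Y_all - mu
  baseline <- new_shift_estimate(mu, base_eif,
                                 eif_inference(base_eif, mu, cfg$alpha),
                                 delta = 0, n = length(Y_all),
                                 condition = "baseline")
  interaction <- if (cfg$approach == "delta") {
    est <- interaction_delta_method(joint, marg_i, marg_j, baseline,
                                    pair = c(var1, var2), alpha = cfg$alpha)
    est$deltas <- delta_bar
    est
  } else {
    pool_interaction_direct(stacks, c(var1, var2), delta_bar,
                            cfg$fluctuation, cfg$alpha)
  }
  list(marg_i = marg_i, marg_j = marg_j, joint = joint, baseline = baseline,
       interaction = interaction, delta_bar = delta_bar,
       fold_pairs = pairs_k)
}

pool_marginals <- function(fold_records, cfg) {
  ok <- !vapply(fold_records, is.null, logical(1))
  if (!all(ok)) stop("missing rank in a fold: cannot pool")
  stacks <- lapply(fold_records, `[[`, "stack")
  delta_bar <- mean(vapply(fold_records, `[[`, numeric(1), "delta"))
  exps <- vapply(fold_records, `[[`, character(1), "exposure")
  label <- paste(unique(exps), collapse = "/")
  est <- pool_shift(stacks, label, delta_bar, cfg$fluctuation, cfg$alpha)
  Y_all <- unlist(lapply(stacks, `[[`, "Y"))
  mu <- mean(Y_all)
  baseline <- new_shift_estimate(mu, Y_all - mu,
                                 eif_inference(Y_all - mu, mu, cfg$alpha),
                                 delta = 0, n = length(Y_all),
                                 condition = "baseline")
  list(estimate = est, baseline = baseline, delta_bar = delta_bar,
       fold_exposures = exps)
}
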