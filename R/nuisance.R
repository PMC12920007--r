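# Nuisance estimation: the outcome regression Qbar(A, W) = E[Y | A, W] and
# the shift density ratio H_delta(A, W) = g0(A - delta | W) / g0(A | W).

nuisance_design <- function(A, W) {
  X <- cbind(A, W)
  colnames(X) <- c(colnames(A), colnames(W))
  # second-order learners expand exposures only, staying linear in W
  attr(X, "expand_cols") <- colnames(A)
  X
}

#' Fit the outcome regression by discrete cross-validated selection
#'
#' Fits \eqn{\bar{Q}(A, W) = E[Y \mid A, W]} by selecting, via V-fold
#' cross-validation, the roster member with the smallest squared-error loss
#' (continuous outcomes) or log loss (binary outcomes), then refitting the
#' winner on all of `train`. Outcome-scaling constants mapping Y onto the
#' unit interval are recorded for the logistic fluctuation: `(0, 1)` for
#' binary outcomes, and `(min Y - m, max Y + m)` with margin
#' `m = 0.1 * range(Y)` otherwise.
#'
#' @param train A `mixture_dataset`.
#' @param roster Character vector of learner names (see [get_learner()]).
#' @param V Number of cross-validation folds for learner selection.
#' @param seed Optional integer seed for the fold draw.
#'
#' @return An `outcome_model` with the selected fit, the CV loss table and
#'   the scaling constants `y_lo`, `y_hi`.
#' @export
fit_outcome_regression <- function(train, roster = default_roster(),
                                   V = 5L, seed = NULL) {
  stopifnot(inherits(train, "mixture_dataset"))
  if (stats::var(train$Y) == 0) stop("degenerate outcome: zero variance")
  if (train$n < 2L * V) stop("need n >= 2V for learner selection")
  X <- nuisance_design(train$A, train$W)
  sel <- cv_select_learner(X, train$Y, roster, V = V, seed = seed,
                           binary = train$binary_outcome)
  if (train$binary_outcome) {
    y_lo <- 0; y_hi <- 1
  } else {
    m <- 0.1 * diff(range(train$Y))
    y_lo <- min(train$Y) - m
    y_hi <- max(train$Y) + m
  }
  structure(
    list(sel = sel, y_lo = y_lo, y_hi = y_hi,
         binary = train$binary_outcome,
         exposures = train$exposures, covariates = train$covariates),
    class = "outcome_model"
  )
}

#' Predict from a fitted outcome regression
#'
#' @param object An `outcome_model`.
#' @param dataset A `mixture_dataset` supplying W (and A unless overridden).
#' @param exposures Optional exposure matrix at which to evaluate (e.g. the
#'   post-intervention exposures from [apply_shift()]); defaults to the
#'   observed exposures.
#' @param scale `"natural"` for the outcome scale, `"unit"` for the
#'   \[0, 1\]-rescaled scale bounded away from \{0, 1\}.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.outcome_model <- function(object, dataset, exposures = NULL,
                                  scale = c("natural", "unit"), ...) {
  scale <- match.arg(scale)
  A <- exposures %||% dataset$A
  X <- nuisance_design(A[, object$exposures, drop = FALSE],
                       dataset$W[, object$covariates, drop = FALSE])
  pred <- object$sel$predict_fun(object$sel$fit, X)
  if (scale == "natural") return(pred)
  # unit scale (used by the logistic fluctuation) is bounded away from {0, 1}
  bound((pred - object$y_lo) / (object$y_hi - object$y_lo),
        .QBOUNDS[1], .QBOUNDS[2])
}

to_unit <- function(object, y) {
  bound((y - object$y_lo) / (object$y_hi - object$y_lo), 0, 1)
}
from_unit <- function(object, u) object$y_lo + (object$y_hi - object$y_lo) * u

#' Estimate the shift density ratio by probabilistic classification
#'
#' Recasts density-ratio estimation as binary classification on an augmented
#' dataset: each observation contributes one row labelled 0 with its observed
#' exposures and one row labelled 1 with its post-intervention exposures
#' \eqn{A + \delta}. With balanced classes, the fitted odds
#' \eqn{p/(1-p)} at \eqn{(a, w)} estimate the ratio
#' \eqn{g_0(a - \delta \mid w) / g_0(a \mid w)}, the clever covariate of the
#' shifted-mean parameter.
#'
#' @param train A `mixture_dataset`.
#' @param spec A `shift_spec` (possibly joint over several exposures; joint
#'   ratios are learned by a single classifier on the jointly shifted copies).
#' @param roster Learner names for the classifier.
#' @param V CV folds for learner selection.
#' @param seed Optional seed.
#' @param ceiling Truncation ceiling \eqn{\lambda} for the ratio.
#'
#' @return A `ratio_model` (method `"classifier"`).
#' @export
fit_ratio_classifier <- function(train, spec, roster = default_roster(),
                                 V = 5L, seed = NULL,
                                 ceiling = .RATIO_CEILING) {
  check_spec(train, spec)
  A1 <- apply_shift(train, spec, mode = "post-intervention")
  X <- rbind(nuisance_design(train$A, train$W), nuisance_design(A1, train$W))
  attr(X, "expand_cols") <- train$exposures  # rbind drops attributes
  xi <- c(rep(0, train$n), rep(1, train$n))
  sel <- cv_select_learner(X, xi, roster, V = V, seed = seed, binary = TRUE)
  structure(
    list(method = "classifier", sel = sel, spec = spec,
         bounds = c(.RATIO_FLOOR, ceiling),
         exposures = train$exposures, covariates = train$covariates),
    class = "ratio_model"
  )
}

#' Estimate the shift density ratio by direct conditional-density modelling
#'
#' Fits a homoscedastic location model per targeted exposure: the exposure is
#' regressed on W (learner chosen by cross-validation from `roster`), and a
#' Gaussian kernel density with Silverman bandwidth is placed on the
#' residuals, giving \eqn{\hat g(a \mid w) = \hat f(a - \hat m(w))}. The
#' ratio is evaluated as \eqn{\hat g(a - \delta \mid w) / \hat g(a \mid w)};
#' for a joint specification the per-exposure ratios multiply.
#'
#' @inheritParams fit_ratio_classifier
#' @param roster Learner names for the location regressions.
#' @return A `ratio_model` (method `"direct"`).
#' @export
fit_conditional_density <- function(train, spec, roster = c("mean", "glm"),
                                    V = 5L, seed = NULL,
                                    ceiling = .RATIO_CEILING) {
  check_spec(train, spec)
  fits <- lapply(seq_along(spec$targets), function(j) {
    tg <- spec$targets[j]
    a <- train$A[, tg]
    sel <- cv_select_learner(train$W, a, roster, V = V,
                             seed = child_seed(seed, j), binary = FALSE)
    r <- a - sel$predict_fun(sel$fit, train$W)
    if (stats::var(r) == 0) stop("zero residual variance for exposure ", tg)
    list(target = tg, sel = sel, resid = r, bw = stats::bw.nrd0(r))
  })
  names(fits) <- spec$targets
  structure(
    list(method = "direct", fits = fits, spec = spec,
         bounds = c(.RATIO_FLOOR, ceiling),
         exposures = train$exposures, covariates = train$covariates),
    class = "ratio_model"
  )
}

# Gaussian KDE evaluated at x, in chunks to bound memory at large n.
kde_eval <- function(x, resid, bw) {
  out <- numeric(length(x))
  step <- max(1L, floor(5e6 / length(resid)))
  for (start in seq(1L, length(x), by = step)) {
    idx <- start:min(start + step - 1L, length(x))
    out[idx] <- rowMeans(outer(x[idx], resid,
                               function(a, b) stats::dnorm(a, b, bw)))
  }
  out
}

#' Evaluate a fitted density-ratio model
#'
#' Returns the truncated ratio \eqn{\hat g(a - \delta \mid w)/\hat g(a \mid w)}
#' at arbitrary exposure values (by default, the observed exposures of
#' `dataset`).
#'
#' @param object A `ratio_model`.
#' @param dataset A `mixture_dataset` supplying W (and A unless overridden).
#' @param exposures Optional exposure matrix at which to evaluate.
#' @param ... Unused.
#' @return Numeric vector of truncated ratios, with attribute `max_ratio`
#'   (the pre-truncation maximum, for positivity diagnostics).
#' @export
predict.ratio_model <- function(object, dataset, exposures = NULL, ...) {
  A <- exposures %||% dataset$A
  W <- dataset$W[, object$covariates, drop = FALSE]
  if (object$method == "classifier") {
    X <- nuisance_design(A[, object$exposures, drop = FALSE], W)
    p <- bound(object$sel$predict_fun(object$sel$fit, X),
               .PBOUNDS[1], .PBOUNDS[2])
    raw <- p / (1 - p)
  } else {
    raw <- rep(1, nrow(A))
    for (f in object$fits) {
      mu <- f$sel$predict_fun(f$sel$fit, W)
      a <- A[, f$target]
      d <- object$spec$delta[[f$target]]
      num <- kde_eval(a - d - mu, f$resid, f$bw)
      den <- kde_eval(a - mu, f$resid, f$bw)
      raw <- raw * (pmax(num, .Machine$double.xmin) /
                      pmax(den, .Machine$double.xmin))
    }
  }
  out <- bound(raw, object$bounds[1], object$bounds[2])
  attr(out, "max_ratio") <- max(raw)
  out
}

#' Clever covariate for a shift intervention
#'
#' Evaluates the truncated density ratio
#' \eqn{H_\delta(A_i, W_i) = g_0(A_i - \delta \mid W_i)/g_0(A_i \mid W_i)}
#' on the observed rows of `dataset`.
#'
#' @param model A `ratio_model` trained for `spec`.
#' @param dataset A `mixture_dataset`.
#' @param spec The `shift_spec` the model was trained for (consistency check).
#' @return Numeric vector of length n with attribute `max_ratio`.
#' @export
clever_covariate <- function(model, dataset, spec = model$spec) {
  stopifnot(inherits(model, "ratio_model"))
  if (!identical(sort(spec$targets), sort(model$spec$targets)) ||
      !isTRUE(all.equal(spec$delta[sort(spec$targets)],
                        model$spec$delta[sort(model$spec$targets)]))) {
    stop("ratio model was trained for a different shift specification")
  }
  predict(model, dataset)
}

#' Fit a density-ratio model by either supported method
#'
#' @inheritParams fit_ratio_classifier
#' @param method `"classifier"` or `"direct"`.
#' @return A `ratio_model`.
#' @export
fit_ratio <- function(train, spec, method = c("classifier", "direct"),
                      roster = NULL, V = 5L, seed = NULL,
                      ceiling = .RATIO_CEILING) {
  method <- match.arg(method)
  if (method == "classifier") {
    fit_ratio_classifier(train, spec, roster = roster %||% default_roster(),
                         V = V, seed = seed, ceiling = ceiling)
  } else {
    fit_conditional_density(train, spec, roster = roster %||% c("mean", "glm"),
                            V = V, seed = seed, ceiling = ceiling)
  }
}
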