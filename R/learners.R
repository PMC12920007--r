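# Learner roster for nuisance estimation. Each learner is a small
# fit/predict pair over a numeric design matrix; selection among them is by
# discrete V-fold cross-validation (squared error for continuous targets,
# log loss for binary ones), i.e. a discrete super learner.

# Second-order expansion: main terms for every column, plus squares and all
# pairwise products of the columns named by the design's "expand_cols"
# attribute (set by the nuisance module to the exposure columns, keeping the
# fit linear in confounders); all columns expand when the attribute is
# absent.
expand_twoway <- function(X) {
  keep <- attr(X, "expand_cols") %||% colnames(X)
  X <- as.matrix(X)
  E <- X[, intersect(keep, colnames(X)), drop = FALSE]
  p <- ncol(E)
  sq <- E^2
  colnames(sq) <- paste0(colnames(E), "_sq")
  out <- cbind(X, sq)
  if (p >= 2L) {
    pairs <- utils::combn(p, 2L)
    prods <- E[, pairs[1L, ], drop = FALSE] * E[, pairs[2L, ], drop = FALSE]
    colnames(prods) <- paste0(colnames(E)[pairs[1L, ]], "_x_",
                              colnames(E)[pairs[2L, ]])
    out <- cbind(out, prods)
  }
  out
}

# Rank-safe (generalized) linear fit on an explicit design matrix; aliased
# coefficients are zeroed for prediction.
fit_lin <- function(X, y, binary) {
  Xd <- cbind(`(Intercept)` = 1, as.matrix(X))
  fam <- if (binary) stats::binomial() else stats::gaussian()
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = fam, control = list(maxit = 50))
  )
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(coef = cf, binary = binary)
}

predict_lin <- function(object, X) {
  Xd <- cbind(1, as.matrix(X))
  eta <- drop(Xd %*% object$coef)
  if (object$binary) expit(eta) else eta
}

#' Retrieve a learner by name
#'
#' Available learners: `"mean"` (intercept-only), `"glm"` (main-terms
#' generalized linear model), `"glm_twoway"` (GLM with squares and all
#' pairwise products), `"ranger"` (random forest), `"xgboost"` (gradient
#' boosting). Each returns probabilities for binary targets and conditional
#' means otherwise.
#'
#' @param name Learner name.
#' @return A list with `name`, `fit(X, y, binary)` and `predict(fit, X)`.
#' @export
get_learner <- function(name) {
  switch(
    name,
    mean = list(
      name = "mean",
      fit = function(X, y, binary) list(mu = mean(y)),
      predict = function(fit, X) rep(fit$mu, nrow(as.matrix(X)))
    ),
    glm = list(
      name = "glm",
      fit = function(X, y, binary) fit_lin(X, y, binary),
      predict = function(fit, X) predict_lin(fit, X)
    ),
    glm_twoway = list(
      name = "glm_twoway",
      fit = function(X, y, binary) fit_lin(expand_twoway(X), y, binary),
      predict = function(fit, X) predict_lin(fit, expand_twoway(X))
    ),
    ranger = list(
      name = "ranger",
      fit = function(X, y, binary) {
        df <- as.data.frame(X)
        ranger::ranger(
          x = df, y = y, num.trees = 200L, min.node.size = 10L,
          num.threads = 1L, seed = 1L
        )
      },
      predict = function(fit, X) {
        p <- stats::predict(fit, data = as.data.frame(X),
                            num.threads = 1L)$predictions
        as.numeric(p)
      }
    ),
    xgboost = list(
      name = "xgboost",
      fit = function(X, y, binary) {
        xgboost::xgboost(
          data = as.matrix(X), label = y, nrounds = 60L, max_depth = 3L,
          eta = 0.3,
          objective = if (binary) "binary:logistic" else "reg:squarederror",
          verbose = 0, nthread = 1L
        )
      },
      predict = function(fit, X) {
        as.numeric(stats::predict(fit, as.matrix(X)))
      }
    ),
    stop("unknown learner: ", name)
  )
}

#' Default learner rosters
#'
#' The default roster for both nuisance functions holds an intercept-only
#' model, a main-terms GLM, a random forest and gradient boosting, selected
#' among by discrete cross-validation. `fast = TRUE` swaps the tree
#' ensembles for a second-order GLM, a roster suited to repeated simulation
#' runs.
#'
#' @param fast Use the lightweight roster.
#' @return Character vector of learner names.
#' @export
default_roster <- function(fast = FALSE) {
  if (fast) c("mean", "glm", "glm_twoway")
  else c("mean", "glm", "ranger", "xgboost")
}

cv_loss <- function(y, pred, binary) {
  if (binary) {
    p <- bound(pred, .PBOUNDS[1], .PBOUNDS[2])
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((y - pred)^2)
  }
}

# Discrete super learner: V-fold CV loss per roster member, winner refit on
# the full data. Returns the fitted winner plus the CV loss table.
cv_select_learner <- function(X, y, roster, V = 5L, seed = NULL,
                              binary = FALSE) {
  n <- length(y)
  stopifnot(n >= 2L * V)
  folds <- with_seed(seed, sample(rep_len(seq_len(V), n)))
  ec <- attr(X, "expand_cols")
  take <- function(rows) {
    Xs <- X[rows, , drop = FALSE]
    attr(Xs, "expand_cols") <- ec  # matrix subsetting drops attributes
    Xs
  }
  losses <- vapply(roster, function(nm) {
    lrn <- get_learner(nm)
    preds <- numeric(n)
    for (v in seq_len(V)) {
      tr <- folds != v
      fit_v <- lrn$fit(take(tr), y[tr], binary)
      preds[!tr] <- lrn$predict(fit_v, take(!tr))
    }
    cv_loss(y, preds, binary)
  }, numeric(1))
  best <- roster[which.min(losses)]
  lrn <- get_learner(best)
  list(
    learner = best,
    fit = lrn$fit(X, y, binary),
    predict_fun = lrn$predict,
    cv_losses = losses,
    roster = roster
  )
}
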