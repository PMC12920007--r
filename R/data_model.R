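#' Construct a validated mixture dataset
#'
#' Bundles the observed triples \eqn{O = (W, A, Y)} — confounders, continuous
#' exposures and outcome — into a validated container used throughout the
#' package. All values must be finite; exposure names must be unique. The
#' outcome is flagged binary exactly when every value lies in \{0, 1\}.
#'
#' @param data A data.frame holding all declared columns.
#' @param covariates Character vector of confounder column names (W).
#' @param exposures Character vector of exposure column names (A); at least one.
#' @param outcome Single outcome column name (Y).
#'
#' @return An object of class `mixture_dataset` with elements `W` (n x q
#'   matrix), `A` (n x p matrix with column names), `Y` (numeric vector),
#'   `binary_outcome` (logical) and `n`.
#'
#' @examples
#' d <- data.frame(w1 = rnorm(5), a1 = runif(5), a2 = runif(5),
#'                 y = rbinom(5, 1, 0.5))
#' md <- mixture_dataset(d, covariates = "w1", exposures = c("a1", "a2"),
#'                       outcome = "y")
#' md$binary_outcome
#' @export
mixture_dataset <- function(data, covariates, exposures, outcome) {
  stopifnot(is.data.frame(data), length(outcome) == 1L, length(exposures) >= 1L)
  declared <- c(covariates, exposures, outcome)
  missing_cols <- setdiff(declared, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(exposures)) {
    stop("duplicate exposure name(s): ",
         paste(unique(exposures[duplicated(exposures)]), collapse = ", "))
  }
  W <- as.matrix(data[, covariates, drop = FALSE])
  A <- as.matrix(data[, exposures, drop = FALSE])
  Y <- as.numeric(data[[outcome]])
  storage.mode(W) <- "double"
  storage.mode(A) <- "double"
  n <- length(Y)
  if (n < 1L) stop("dataset must have at least one row")
  for (nm in list(list(W, "W"), list(A, "A"), list(Y, "Y"))) {
    if (!all(is.finite(nm[[1]]))) {
      stop("non-finite value in ", nm[[2]], " columns")
    }
  }
  colnames(A) <- exposures
  colnames(W) <- covariates
  structure(
    list(W = W, A = A, Y = Y,
         binary_outcome = all(Y %in% c(0, 1)),
         n = n,
         covariates = covariates, exposures = exposures, outcome = outcome),
    class = "mixture_dataset"
  )
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat(sprintf("mixture_dataset: n = %d, %d confounder(s), %d exposure(s), %s outcome\n",
              x$n, ncol(x$W), ncol(x$A),
              if (x$binary_outcome) "binary" else "continuous"))
  cat("  exposures:", paste(x$exposures, collapse = ", "), "\n")
  invisible(x)
}

#' Read a mixture dataset from CSV with declared column roles
#'
#' @param path Path to a CSV file.
#' @inheritParams mixture_dataset
#' @return A `mixture_dataset`.
#' @export
read_mixture_csv <- function(path, covariates, exposures, outcome) {
  raw <- utils::read.csv(path, check.names = FALSE)
  mixture_dataset(raw, covariates = covariates, exposures = exposures,
                  outcome = outcome)
}

#' Specify a stochastic shift intervention
#'
#' A shift specification names the exposures to intervene on and the signed
#' shift \eqn{\delta} for each. The intervention replaces each targeted
#' exposure \eqn{A} by \eqn{A + \delta} (a regulatory reduction of one unit is
#' `delta = -1`); the post-intervention exposure density is then
#' \eqn{g_\delta(a \mid w) = g_0(a - \delta \mid w)}. Non-targeted exposures
#' are implicitly shifted by zero.
#'
#' @param targets Character vector of exposure names to shift.
#' @param delta Numeric shift per target (recycled if scalar); finite. A zero
#'   delta makes the target equivalent to an untouched exposure and is allowed
#'   so that degenerate (no-shift) interventions can be expressed.
#'
#' @return An object of class `shift_spec`: named numeric vector of deltas
#'   plus the additive-convention tag.
#' @export
shift_spec <- function(targets, delta) {
  stopifnot(is.character(targets), length(targets) >= 1L)
  if (anyDuplicated(targets)) stop("duplicate shift target")
  delta <- rep_len(as.numeric(delta), length(targets))
  if (!all(is.finite(delta))) {
    stop("each delta must be finite")
  }
  names(delta) <- targets
  structure(list(targets = targets, delta = delta, convention = "additive"),
            class = "shift_spec")
}

#' @export
print.shift_spec <- function(x, ...) {
  cat("shift_spec (additive):",
      paste(sprintf("%s %+g", x$targets, x$delta), collapse = ", "), "\n")
  invisible(x)
}

check_spec <- function(dataset, spec) {
  stopifnot(inherits(dataset, "mixture_dataset"), inherits(spec, "shift_spec"))
  unknown <- setdiff(spec$targets, dataset$exposures)
  if (length(unknown) > 0L) {
    stop("unknown shift target(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Apply a shift specification to the exposure matrix
#'
#' Two evaluation modes arise in shift-based estimation:
#' `"post-intervention"` adds each \eqn{\delta} to its target column — the
#' exposure values at which the outcome regression is evaluated for the
#' substitution term; `"density-argument"` subtracts each \eqn{\delta} — the
#' argument at which the observed-data density \eqn{g_0} is evaluated to
#' obtain the shifted density \eqn{g_\delta}. Non-target columns are returned
#' unchanged.
#'
#' @param dataset A `mixture_dataset`, or a bare exposure matrix with named
#'   columns.
#' @param spec A `shift_spec`.
#' @param mode `"post-intervention"` (default) or `"density-argument"`.
#' @return The exposure matrix after shifting.
#' @export
apply_shift <- function(dataset, spec,
                        mode = c("post-intervention", "density-argument")) {
  mode <- match.arg(mode)
  A <- if (inherits(dataset, "mixture_dataset")) dataset$A else as.matrix(dataset)
  stopifnot(inherits(spec, "shift_spec"))
  unknown <- setdiff(spec$targets, colnames(A))
  if (length(unknown) > 0L) {
    stop("unknown shift target(s): ", paste(unknown, collapse = ", "))
  }
  sgn <- if (mode == "post-intervention") 1 else -1
  for (tg in spec$targets) {
    A[, tg] <- A[, tg] + sgn * spec$delta[[tg]]
  }
  A
}

#' Subset the rows of a mixture dataset
#'
#' @param dataset A `mixture_dataset`.
#' @param idx Integer row indices.
#' @return A `mixture_dataset` restricted to `idx`.
#' @export
subset_rows <- function(dataset, idx) {
  stopifnot(inherits(dataset, "mixture_dataset"))
  out <- dataset
  out$W <- dataset$W[idx, , drop = FALSE]
  out$A <- dataset$A[idx, , drop = FALSE]
  out$Y <- dataset$Y[idx]
  out$n <- length(idx)
  out
}
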