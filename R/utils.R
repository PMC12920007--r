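# Internal numerical helpers shared across modules.

# Probability bounds used when mapping outcomes / predictions to the unit
# interval before a logistic fluctuation.
.QBOUNDS <- c(1e-4, 1 - 1e-4)
# Bounds applied to classifier probabilities before forming odds.
.PBOUNDS <- c(1e-6, 1 - 1e-6)
# Default density-ratio truncation: floor and ceiling (lambda).
.RATIO_FLOOR <- 1e-6
.RATIO_CEILING <- 50

bound <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
logit <- function(p) stats::qlogis(p)

#' @noRd
expit <- function(x) stats::plogis(x)

# Deterministic child-seed fan-out: one master seed spawns per-fold and
# per-replicate streams without overlap. Kept below 2^31 - 1.
child_seed <- function(seed, index, stream = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729 +
                as.numeric(stream) * 15485863) %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
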