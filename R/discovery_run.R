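# The end-to-end K-fold discovery-estimation engine.

#' Run K-fold discovery and CV-TMLE estimation
#'
#' Per fold: the outcome regression is fitted on the training rows; all
#' exposure pairs are ranked by the g-computation interaction contrast (and,
#' optionally, single exposures by their shift contrast); shifts are adapted
#' on the training rows until the density ratio respects the positivity
#' ceiling; and the discovered parameters are estimated by TMLE on the
#' validation rows with the training-fold nuisances (CV-TMLE). Fold
#' estimates are pooled by rank through a single targeting step over the
#' stacked validation predictions, paired with the average adapted shift
#' \eqn{\bar\delta}.
#'
#' @param data A `mixture_dataset`.
#' @param config A `shift_config` (or arguments for one, as a list).
#' @return A `discovery_result`: tidy `table` of fold and pooled rows,
#'   per-fold records, pooled estimates per block, per-fold rankings, the
#'   discovery consistency tables, the fold plan, and a run manifest.
#' @export
run_discovery_estimation <- function(data, config = shift_config()) {
  stopifnot(inherits(data, "mixture_dataset"))
  cfg <- if (inherits(config, "shift_config")) config
  else do.call(shift_config, config)
  delta_map <- expand_delta_map(cfg$delta, data$exposures)
  plan <- make_folds(data$n, cfg$K, seed = child_seed(cfg$seed, 0L))

  ranked <- vector("list", cfg$K)
  marg_rank <- vector("list", cfg$K)
  recs <- list(synergy = list(), antagonism = list(),
               marginal_positive = list(), marginal_negative = list())
  failures <- list()

  for (k in seq_len(cfg$K)) {
    train <- subset_rows(data, plan$folds[[k]]$train)
    valid <- subset_rows(data, plan$folds[[k]]$valid)
    Q_k <- fit_outcome_regression(train, cfg$q_roster, V = cfg$V,
                                  seed = child_seed(cfg$seed, k, 1L))
    ranked[[k]] <- rank_pairs(train, Q_k, delta_map, s = cfg$s)

    ratio_factory <- function(spec) {
      fit_ratio(train, spec, cfg$density_method, cfg$g_roster, cfg$V,
                seed = child_seed(cfg$seed, k, 2L), ceiling = cfg$lambda)
    }
    est_pair <- function(row) {
      pair <- c(row$exposure_i, row$exposure_j)
      req <- shift_spec(pair, delta_map[pair])
      ad <- adapt_delta(train, req, ratio_factory, lambda = cfg$lambda)
      dd <- unname(ad$spec$delta)
      ratios <- list(
        joint = ad$model,
        i = ratio_factory(shift_spec(pair[1], dd[1])),
        j = ratio_factory(shift_spec(pair[2], dd[2]))
      )
      estimate_pair_fold(valid, pair, dd, Q_k, ratios, cfg, k)
    }
    for (set in c("synergy", "antagonism")) {
      found <- ranked[[k]][[set]]
      for (r in seq_len(cfg$s)) {
        slot <- paste0(set, r)
        if (is.null(recs[[set]][[slot]])) recs[[set]][[slot]] <- list()
        rec <- if (nrow(found) >= r) {
          tryCatch(est_pair(found[r, ]), error = function(e) {
            failures[[length(failures) + 1L]] <<-
              list(fold = k, block = set, rank = r,
                   message = conditionMessage(e))
            NULL
          })
        } else {
          failures[[length(failures) + 1L]] <-
            list(fold = k, block = set, rank = r,
                 message = "no pair with the required sign discovered")
          NULL
        }
        recs[[set]][[slot]][k] <- list(rec)  # keep NULL slots (failed folds)
      }
    }

    if (cfg$marginals) {
      shifts <- vapply(data$exposures, function(e)
        gcomp_shift(Q_k, train, shift_spec(e, delta_map[[e]])), numeric(1))
      marg_rank[[k]] <- shifts
      est_marg <- function(e) {
        req <- shift_spec(e, delta_map[[e]])
        ad <- adapt_delta(train, req, ratio_factory, lambda = cfg$lambda)
        estimate_marginal_fold(valid, e, unname(ad$spec$delta), Q_k,
                               ad$model, cfg, k)
      }
      for (side in c("marginal_positive", "marginal_negative")) {
        pick <- if (side == "marginal_positive") {
          if (max(shifts) > 0) names(which.max(shifts)) else NULL
        } else {
          if (min(shifts) < 0) names(which.min(shifts)) else NULL
        }
        if (is.null(recs[[side]][["1"]])) recs[[side]][["1"]] <- list()
        rec <- if (!is.null(pick)) {
          tryCatch(est_marg(pick), error = function(e) {
            failures[[length(failures) + 1L]] <<-
              list(fold = k, block = side, rank = 1L,
                   message = conditionMessage(e))
            NULL
          })
        } else {
          failures[[length(failures) + 1L]] <-
            list(fold = k, block = side, rank = 1L,
                 message = "no exposure with the required sign")
          NULL
        }
        recs[[side]][["1"]][k] <- list(rec)
      }
    }
  }

  pooled <- list()
  for (set in c("synergy", "antagonism")) {
    pooled[[set]] <- lapply(recs[[set]], function(fr) {
      if (length(fr) < cfg$K) fr[(length(fr) + 1L):cfg$K] <- list(NULL)
      if (cfg$pool_by == "pair") {
        # realign by the modal discovered pair: pool only the folds that
        # discovered it (rank alignment is the default; see vignette)
        keys <- vapply(fr, function(r)
          if (is.null(r)) NA_character_ else paste(r$pair, collapse = "*"),
          character(1))
        if (all(is.na(keys))) return(NULL)
        modal <- names(which.max(table(keys)))
        fr <- fr[!is.na(keys) & keys == modal]
      }
      tryCatch(pool_folds(fr, cfg), error = function(e) NULL)
    })
  }
  if (cfg$marginals) {
    for (side in c("marginal_positive", "marginal_negative")) {
      pooled[[side]] <- lapply(recs[[side]], function(fr) {
        if (length(fr) < cfg$K) fr[(length(fr) + 1L):cfg$K] <- list(NULL)
        tryCatch(pool_marginals(fr, cfg), error = function(e) NULL)
      })
    }
  }

  res <- structure(
    list(table = NULL, folds = recs, pooled = pooled, ranked = ranked,
         marginal_rank = marg_rank,
         consistency = list(
           synergy = tryCatch(rank_consistency(ranked, "synergy"),
                              error = function(e) NULL),
           antagonism = tryCatch(rank_consistency(ranked, "antagonism"),
                                 error = function(e) NULL)
         ),
         failures = failures, fold_plan = plan, config = cfg,
         n = data$n),
    class = "discovery_result"
  )
  res$table <- result_table(res)
  res
}

fmt_delta <- function(d) paste(format(unname(d), digits = 6, trim = TRUE),
                               collapse = ",")

# Result tables report shifted means as changes versus the baseline mean
# outcome (E_delta[Y] - E[Y]), with the EIF of the difference for the SE.
contrast_vs_baseline <- function(est, base) {
  psi <- est$psi - base$psi
  eif <- est$eif - base$eif
  new_shift_estimate(psi, eif, eif_inference(eif, psi),
                     delta = est$delta, n = est$n, fold = est$fold,
                     condition = est$condition, epsilon = est$epsilon,
                     converged = est$converged)
}

estimate_row <- function(block, rank, condition, est, fold, n) {
  data.frame(
    block = block, rank = rank, condition = condition,
    psi = est$psi %||% est$psi_int,
    variance = est$se^2, se = est$se,
    ci_lo = est$ci_lo, ci_hi = est$ci_hi, p_value = est$p_value,
    fold = fold, n = n, delta = fmt_delta(est$delta %||% est$deltas),
    stringsAsFactors = FALSE
  )
}

#' Tidy result table for a discovery-estimation run
#'
#' One row per estimated condition: for each discovered pair, the two
#' marginal shifts, the joint shift and the interaction contrast, per fold
#' and pooled; for each discovered marginal exposure, its shifted mean
#' difference from baseline is reported as the shifted-mean estimate itself.
#' Columns: `block`, `rank`, `condition`, `psi`, `variance`, `se`, `ci_lo`,
#' `ci_hi`, `p_value`, `fold`, `n`, `delta`.
#'
#' @param res A `discovery_result`.
#' @return A data.frame.
#' @export
result_table <- function(res) {
  cfg <- res$config
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  for (set in names(res$folds)) {
    for (slot in names(res$folds[[set]])) {
      fr <- res$folds[[set]][[slot]]
      rank <- as.integer(gsub("\\D", "", slot))
      if (length(rank) == 0L || is.na(rank)) rank <- 1L
      for (k in seq_along(fr)) {
        rec <- fr[[k]]
        if (is.null(rec)) next
        if (!is.null(rec$pair)) {
          add(estimate_row(set, rank, rec$pair[1],
                           contrast_vs_baseline(rec$marg_i, rec$baseline),
                           as.character(k), rec$marg_i$n))
          add(estimate_row(set, rank, rec$pair[2],
                           contrast_vs_baseline(rec$marg_j, rec$baseline),
                           as.character(k), rec$marg_j$n))
          add(estimate_row(set, rank, "Joint",
                           contrast_vs_baseline(rec$joint, rec$baseline),
                           as.character(k), rec$joint$n))
          add(estimate_row(set, rank, "Interaction", rec$interaction,
                           as.character(k), rec$interaction$n))
        } else {
          add(estimate_row(set, rank, rec$exposure,
                           contrast_vs_baseline(rec$estimate, rec$baseline),
                           as.character(k), rec$estimate$n))
        }
      }
      pl <- res$pooled[[set]][[slot]]
      if (!is.null(pl)) {
        if (!is.null(pl$interaction)) {
          add(estimate_row(set, rank, pl$marg_i$condition,
                           contrast_vs_baseline(pl$marg_i, pl$baseline),
                           "Pooled", pl$marg_i$n))
          add(estimate_row(set, rank, pl$marg_j$condition,
                           contrast_vs_baseline(pl$marg_j, pl$baseline),
                           "Pooled", pl$marg_j$n))
          add(estimate_row(set, rank, "Joint",
                           contrast_vs_baseline(pl$joint, pl$baseline),
                           "Pooled", pl$joint$n))
          add(estimate_row(set, rank, "Interaction", pl$interaction,
                           "Pooled", pl$interaction$n))
        } else {
          add(estimate_row(set, rank, pl$estimate$condition,
                           contrast_vs_baseline(pl$estimate, pl$baseline),
                           "Pooled", pl$estimate$n))
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(block = character(), rank = integer(),
                      condition = character(), psi = numeric(),
                      variance = numeric(), se = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(),
                      p_value = numeric(), fold = character(),
                      n = integer(), delta = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("discovery_result: n = %d, K = %d, approach = %s\n",
              x$n, x$config$K, x$config$approach))
  if (length(x$failures)) {
    cat(sprintf("  %d fold-level failure(s) reported\n", length(x$failures)))
  }
  pl <- x$pooled$synergy[["synergy1"]]
  if (!is.null(pl)) {
    cat("  pooled rank-1 synergy interaction: ")
    print(pl$interaction)
  }
  invisible(x)
}
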