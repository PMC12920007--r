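test_that("fold plans are balanced, disjoint, exhaustive and reproducible", {
  fp <- make_folds(500, 3, seed = 1)
  sizes <- sort(vapply(fp$folds, function(f) length(f$valid), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(167L, 167L, 166L))
  valid_all <- sort(unlist(lapply(fp$folds, `[[`, "valid")))
  expect_equal(valid_all, 1:500)
  for (f in fp$folds) {
    expect_length(intersect(f$train, f$valid), 0)
    expect_equal(sort(c(f$train, f$valid)), 1:500)
  }
  expect_identical(make_folds(500, 3, seed = 1), fp)
  # leave-one-out at K = n
  loo <- make_folds(10, 10, seed = 2)
  expect_true(all(vapply(loo$folds, function(f) length(f$valid),
                         integer(1)) == 1L))
  expect_error(make_folds(5, 6), "exceed")
  expect_error(make_folds(5, 1), "at least 2")
})

test_that("pair ranking evaluates all pairs and applies the sign rule", {
  sc <- sim_scenario(n = 800, synergy = 0.60, seed = 12)
  d <- simulate_dataset(sc)
  Q <- fit_outcome_regression(d, roster = default_roster(fast = TRUE),
                              seed = 1)
  rk <- rank_pairs(d, Q, deltas = 0.5, s = 2)
  expect_equal(nrow(rk$table), 15L)  # choose(6, 2)
  expect_equal(c(rk$synergy$exposure_i[1], rk$synergy$exposure_j[1]),
               c("A1", "A2"))
  expect_equal(c(rk$antagonism$exposure_i[1], rk$antagonism$exposure_j[1]),
               c("A5", "A6"))
  expect_true(all(rk$synergy$value > 0))
  expect_true(all(rk$antagonism$value < 0))

  # additive fitted surface: no pair qualifies under the sign rule
  Q_add <- fit_outcome_regression(d, roster = "glm", seed = 1)
  rk0 <- rank_pairs(d, Q_add, deltas = 0.5, s = 2)
  expect_equal(nrow(rk0$synergy), 0L)
  expect_equal(nrow(rk0$antagonism), 0L)
})

test_that("adaptive shifts shrink on the grid until the ceiling holds", {
  d <- gaussian_exposure_data(800, seed = 9)
  factory <- function(spec) fit_conditional_density(d, spec, seed = 1,
                                                    ceiling = 1e6)
  # small shift already satisfies the ceiling: untouched
  ok <- adapt_delta(d, shift_spec("a1", 0.1), factory, lambda = 50)
  expect_equal(unname(ok$spec$delta), 0.1)
  expect_equal(ok$n_shrink, 0L)

  # large shift: compare against an independent walk down the same grid
  lam <- 5
  ad <- adapt_delta(d, shift_spec("a1", 3), factory, lambda = lam)
  grid_walk <- function() {
    frac <- 1
    repeat {
      mdl <- factory(shift_spec("a1", 3 * frac))
      if (attr(predict(mdl, d), "max_ratio") < lam) return(3 * frac)
      frac <- frac * 0.9
    }
  }
  expect_equal(unname(ad$spec$delta), grid_walk(), tolerance = 1e-12)
  expect_lt(ad$max_ratio, lam)
  expect_gt(ad$n_shrink, 0L)

  # unattainable ceiling errors out at the floor
  expect_error(adapt_delta(d, shift_spec("a1", 3), factory,
                           lambda = 1 + 1e-9),
               "positivity")
})

test_that("rank consistency flags robust pairs across folds", {
  mk <- function(i, j, rank) {
    list(synergy = data.frame(exposure_i = i, exposure_j = j, value = 1,
                              rank = rank),
         antagonism = data.frame(exposure_i = character(),
                                 exposure_j = character(),
                                 value = numeric(), rank = integer()))
  }
  always <- rank_consistency(rep(list(mk("A1", "A2", 1L)), 3), "synergy")
  expect_equal(always$frequency, 3L)
  expect_equal(always$mean_rank, 1)
  expect_true(always$robust)

  once <- rank_consistency(c(list(mk("A1", "A3", 1L)),
                             rep(list(mk("A1", "A2", 1L)), 4)), "synergy")
  expect_false(once$robust[once$exposure_j == "A3"])
  expect_true(once$robust[once$exposure_j == "A2"])

  empty <- rank_consistency(rep(list(mk("A1", "A2", 1L)), 2), "antagonism")
  expect_equal(nrow(empty), 0L)
})

test_that("discovery-estimation produces the full fold and pooled structure", {
  fx <- make_niehs_like_fixture(seed = 2, n = 500)
  cfg <- shift_config(K = 3, delta = 1, seed = 5,
                      q_roster = default_roster(fast = TRUE),
                      g_roster = default_roster(fast = TRUE))
  res <- run_discovery_estimation(fx, cfg)
  tab <- res$table
  expect_setequal(unique(tab$block),
                  c("synergy", "antagonism", "marginal_positive",
                    "marginal_negative"))
  # every completed fold contributes 4 rows per pair block, 1 per marginal
  for (b in c("synergy", "antagonism")) {
    pooled <- tab[tab$block == b & tab$fold == "Pooled", ]
    if (nrow(pooled)) {
      expect_setequal(pooled$condition[3:4], c("Joint", "Interaction"))
      expect_equal(pooled$n[1], fx$n)
    }
  }
  # discovery and estimation rows never overlap within a fold
  for (f in res$fold_plan$folds) {
    expect_length(intersect(f$train, f$valid), 0)
  }
  # determinism: same seed, same estimates
  res2 <- run_discovery_estimation(fx, cfg)
  expect_equal(res2$table$psi, tab$psi, tolerance = 1e-12)
})

test_that("pooling identical folds reproduces the common estimate", {
  sc <- sim_scenario(n = 600, synergy = 0.60, seed = 21)
  d <- simulate_dataset(sc)
  cfg <- fast_cfg(seed = 3)
  res <- run_discovery_estimation(d, cfg)
  rec <- res$folds$synergy$synergy1[[1]]
  expect_false(is.null(rec))
  dup <- pool_folds(list(rec, rec), cfg)
  expect_lt(abs(dup$interaction$psi_int - rec$interaction$psi_int), 0.02)
  # stacking identical pieces shrinks the SE by about sqrt(2)
  expect_lt(abs(dup$interaction$se - rec$interaction$se / sqrt(2)),
            0.1 * rec$interaction$se)
  expect_lte(dup$interaction$se, rec$interaction$se)
  # averaged shift is the arithmetic mean of fold shifts
  r2 <- rec
  r2$deltas <- c(1.0, 1.0)
  rec$deltas <- c(0.8, 0.8)
  r3 <- rec
  r3$deltas <- c(0.9, 0.9)
  expect_equal(unname(pool_folds(list(r2, rec, r3), cfg)$delta_bar),
               c(0.9, 0.9))
  expect_error(pool_folds(list(rec, NULL), cfg), "missing rank")
})

test_that("pair-aligned pooling restricts to the modal discovered pair", {
  sc <- sim_scenario(n = 800, synergy = 0.60, seed = 37)
  d <- simulate_dataset(sc)
  res <- run_discovery_estimation(d, fast_cfg(seed = 4, pool_by = "pair"))
  pl <- res$pooled$synergy[["synergy1"]]
  expect_false(is.null(pl))
  # a single pair identity underlies the pooled row
  expect_equal(nrow(unique(pl$fold_pairs)), 1L)
})

test_that("null generative model yields interaction CIs covering zero", {
  # with no true product terms the discovered "top pair" is noise; force a
  # second-order outcome fit so the data-adaptive parameter always exists
  cfg <- fast_cfg(q_roster = "glm_twoway")
  hits <- vapply(1:15, function(r) {
    sc <- sim_scenario(n = 500, synergy = 0, antagonism = 0,
                       seed = 1000 + r)
    d <- simulate_dataset(sc)
    cfg$seed <- 1000 + r
    cfg$delta <- 0.5
    res <- run_discovery_estimation(d, cfg)
    pl <- res$pooled$synergy[["synergy1"]]
    if (is.null(pl)) return(NA)
    pl$interaction$ci_lo <= 0 && 0 <= pl$interaction$ci_hi
  }, logical(1))
  hits <- hits[!is.na(hits)]
  expect_gte(mean(hits), 0.8)  # ~95% nominal, binomial error at 15 draws
})
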