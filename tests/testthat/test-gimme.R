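test_that("expression maps onto reactions by GPR min/max; exchanges stay unscored", {
  toy <- toy_fixture()
  m <- toy$model
  vals <- stats::setNames(seq_along(m$genes), m$genes)
  sc <- map_expression_to_reactions(m, vals)
  expect_true(all(is.na(sc[exchange_reactions(m)])))
  expect_equal(unname(sc["GLYC"]),
               min(vals[c("glk1", "pfk1")]))           # AND -> min
  expect_equal(unname(sc["ADH"]), max(vals[c("adh1", "adh2")]))  # OR -> max
  expect_true(is.na(sc["NH4t"]))                       # no GPR
  expect_error(map_expression_to_reactions(m, numeric()), "empty")
})

test_that("GIMME removes exactly the decoy branch under the uracil profile", {
  toy <- toy_fixture()
  m <- toy$model
  prof <- make_expression_profiles(m, seed = 11)
  sc_u <- map_expression_to_reactions(m, prof$uracil)
  ctx <- gimme(m, sc_u, toy$media$uracil_n)
  expect_setequal(ctx$removed, toy$truth$decoy_reactions)
  # the orphaned decoy intermediate disappears with its reactions
  expect_true("lac_c" %in% ctx$removed_metabolites)
  # context model still attains the required objective share
  mu_ctx <- fba(ctx$model, toy$media$uracil_n)$objective
  expect_gte(mu_ctx, 0.9 * ctx$parent_objective - 1e-8)
  # unscored reactions are never removed
  expect_length(intersect(ctx$removed, exchange_reactions(m)), 0)
})

test_that("GIMME under the ammonium profile additionally silences the URC branch", {
  toy <- toy_fixture()
  m <- toy$model
  prof <- make_expression_profiles(m, seed = 11)
  sc_a <- map_expression_to_reactions(m, prof$ammonium)
  ctx <- gimme(m, sc_a, toy$media$ammonium_n)
  expect_setequal(ctx$removed,
                  c(toy$truth$decoy_reactions, toy$truth$urc_reactions))
})

test_that("GIMME edge cases: vacuous threshold, binding objective, monotone threshold", {
  toy <- toy_fixture()
  m <- toy$model
  prof <- make_expression_profiles(m, seed = 11)
  sc <- map_expression_to_reactions(m, prof$uracil)
  # threshold below every score: nothing penalized, context = parent
  ctx0 <- gimme(m, sc, toy$media$uracil_n, threshold_percentile = 0)
  expect_length(ctx0$removed, 0)
  expect_equal(n_reactions(ctx0$model), n_reactions(m))
  # infeasible objective requirement errors informatively
  expect_error(gimme(m, sc, toy$media$uracil_n,
                     required_objective_fraction = 1.5), "cannot be met")
  # lowering the percentile never removes more reactions
  removed_at <- vapply(c(5, 15, 25, 40), function(p) {
    length(gimme(m, sc, toy$media$uracil_n, threshold_percentile = p)$removed)
  }, numeric(1))
  expect_true(all(diff(removed_at) >= 0))
})

test_that("interval Jaccard: worked values, symmetry, degenerate conventions, MC estimate", {
  expect_equal(interval_jaccard(c(1, 3), c(1, 3)), 1)
  expect_equal(interval_jaccard(c(0, 1), c(2, 3)), 0)
  expect_equal(interval_jaccard(c(1, 3), c(2, 5)), 0.25)
  expect_equal(interval_jaccard(c(2, 2), c(2, 2)), 1)   # identical points
  expect_equal(interval_jaccard(c(2, 2), c(3, 3)), 0)   # distinct points
  expect_equal(interval_jaccard(c(0, 1), c(1, 2)), 0)   # touching
  set.seed(606)
  for (i in 1:25) {
    a <- sort(stats::runif(2, -5, 5))
    b <- sort(stats::runif(2, -5, 5))
    expect_identical(interval_jaccard(a, b), interval_jaccard(b, a))
    # Monte-Carlo overlap estimate over the union span
    lo <- min(a[1], b[1]); hi <- max(a[2], b[2])
    x <- stats::runif(40000, lo, hi)
    inter <- mean(x >= max(a[1], b[1]) & x <= min(a[2], b[2])) * (hi - lo)
    uni <- mean((x >= a[1] & x <= a[2]) | (x >= b[1] & x <= b[2])) * (hi - lo)
    expect_lt(abs(interval_jaccard(a, b) - inter / uni), 0.01)
  }
})

test_that("differential flux is silent on identical contexts and localizes the URC signal", {
  toy <- toy_fixture()
  m <- toy$model
  prof <- make_expression_profiles(m, seed = 11)
  ctx_u <- gimme(m, map_expression_to_reactions(m, prof$uracil),
                 toy$media$uracil_n)
  ctx_a <- gimme(m, map_expression_to_reactions(m, prof$ammonium),
                 toy$media$ammonium_n)
  # identical contexts, identical media: nothing flagged
  same <- differential_flux(ctx_a, ctx_a, toy$media$ammonium_n,
                            toy$media$ammonium_n)
  expect_identical(sum(same$flagged), 0L)
  expect_length(attr(same, "exclusive_a"), 0)
  # uracil vs ammonium: the nitrogen route and its neighbors light up
  rep <- differential_flux(ctx_u, ctx_a, toy$media$uracil_n,
                           toy$media$ammonium_n)
  flagged <- rep$reaction[rep$flagged]
  expect_true(all(c("URAt", "EX_ura", "NH4t", "EX_nh4", "UREAt") %in% flagged))
  # the URC core itself is context-exclusive (removed from the ammonium model)
  expect_setequal(attr(rep, "exclusive_a"), toy$truth$urc_reactions)
  # central carbon metabolism is not differential
  expect_false(any(c("GLYC", "TCA", "ETC", "EX_glc") %in% flagged))
  expect_true(all(rep$jaccard >= 0 & rep$jaccard <= 1))
})

test_that("pathway ranking counts flagged reactions with deterministic ties", {
  rep <- data.frame(reaction = paste0("r", 1:6),
                    jaccard = c(0, 0, 0, 0, 1, 0),
                    flagged = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
                    subsystem = c("P", "P", "P", "Q", "Q", ""))
  rk <- rank_pathways(rep)
  expect_identical(rk$subsystem, c("P", "Q", "unassigned"))
  expect_identical(rk$n_flagged, c(3L, 1L, 1L))
  expect_equal(sum(rk$fraction), 1)
  # ties break lexicographically
  rep2 <- rep
  rep2$subsystem <- c("zeta", "zeta", "alpha", "alpha", "Q", "beta")
  rk2 <- rank_pathways(rep2)
  expect_identical(rk2$subsystem, c("alpha", "zeta", "beta"))
  # no flags: empty table
  expect_identical(nrow(rank_pathways(rep[rep$jaccard == 1, ])), 0L)
})
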