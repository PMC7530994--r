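test_that("FBA optimum equals brute-force vertex enumeration on small fixtures", {
  mini <- make_mini_model()
  S <- stoichiometric_matrix(mini$model)
  ref <- brute_lp(as.numeric(mini$model$reactions$id == "BIO"), S,
                  numeric(nrow(S)), mini$model$reactions$lb,
                  mini$model$reactions$ub)
  sol <- fba(mini$model)
  expect_equal(sol$objective, ref$objective, tolerance = 1e-8)
  expect_equal(sol$objective, mini$truth$mu_opt, tolerance = 1e-8)
  for (fix in list(chain_deadend_model(), parallel_branch_model(),
                   make_loop_model())) {
    S <- stoichiometric_matrix(fix)
    ref <- brute_lp(as.numeric(fix$reactions$id == fix$biomass), S,
                    numeric(nrow(S)), fix$reactions$lb, fix$reactions$ub)
    expect_equal(fba(fix)$objective, ref$objective, tolerance = 1e-7,
                 label = fix$id)
  }
})

test_that("optimal solutions satisfy steady state and bounds; no carbon means no growth", {
  toy <- toy_fixture()
  sol <- fba(toy$model, toy$media$minimal_glucose)
  S <- stoichiometric_matrix(toy$model)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  m <- apply_medium(toy$model, toy$media$minimal_glucose)
  expect_true(all(sol$fluxes >= m$reactions$lb - 1e-8 &
                  sol$fluxes <= m$reactions$ub + 1e-8))
  carbon_free <- medium("nc", c(EX_h2o = 1000, EX_h = 1000, EX_co2 = 1000,
                                EX_nh4 = 1000, EX_o2 = 1000))
  expect_lt(fba(toy$model, carbon_free)$objective, LK_FLUX_TOL)
})

test_that("toy growth matches the analytic aerobic and oxygen-limited optima", {
  toy <- toy_fixture()
  base <- c(EX_h2o = 1000, EX_h = 1000, EX_co2 = 1000, EX_nh4 = 1000)
  for (g in c(1, 2.28, 5)) {
    aer <- medium("aer", c(base, EX_glc = g, EX_o2 = 1000))
    expect_equal(fba(toy$model, aer)$objective, toy$truth$aerobic_mu(g),
                 tolerance = 1e-8)
    for (w in c(0.25, 1)) {
      ana <- medium("ana", c(base, EX_glc = g, EX_o2 = w))
      expect_equal(fba(toy$model, ana)$objective,
                   toy$truth$anaerobic_mu(g, w), tolerance = 1e-8)
    }
  }
})

test_that("respiratory quotient: printed worked example, equality case, pure respiration", {
  # desk values: CO2 6.4 over O2 6.2 gives 1.03 at two decimals
  v <- c(EX_co2 = 6.4, EX_o2 = -6.2)
  expect_equal(round(respiratory_quotient(v, "EX_co2", "EX_o2"), 2), 1.03)
  expect_equal(respiratory_quotient(c(EX_co2 = 3, EX_o2 = -3),
                                    "EX_co2", "EX_o2"), 1)
  # toy on glucose respires fully: RQ exactly 1
  toy <- toy_fixture()
  sol <- fba(toy$model, toy$media$minimal_glucose)
  expect_equal(respiratory_quotient(sol, "EX_co2", "EX_o2"), 1,
               tolerance = 1e-6)
  expect_error(respiratory_quotient(c(EX_co2 = 1, EX_o2 = 0),
                                    "EX_co2", "EX_o2"), "oxygen")
})

test_that("mass yields follow molar-mass arithmetic and scale invariance", {
  v <- c(EX_etoh = 2, EX_glc = -1)
  y <- product_yield(v, "EX_etoh", "EX_glc", 46.068, 180.156)
  expect_equal(y, 2 * 46.068 / 180.156, tolerance = 1e-12)  # ~0.511 g/g
  expect_equal(round(y, 3), 0.511)
  expect_equal(product_yield(c(EX_etoh = 0, EX_glc = -1), "EX_etoh", "EX_glc",
                             46.068, 180.156), 0)
  # doubling all fluxes leaves the yield (and RQ) unchanged
  expect_equal(product_yield(2 * v, "EX_etoh", "EX_glc", 46.068, 180.156), y)
  v2 <- c(EX_co2 = 6.4, EX_o2 = -6.2)
  expect_equal(respiratory_quotient(2 * v2, "EX_co2", "EX_o2"),
               respiratory_quotient(v2, "EX_co2", "EX_o2"))
  expect_error(product_yield(c(EX_etoh = 1, EX_glc = 0), "EX_etoh", "EX_glc",
                             46, 180), "uptake")
})

test_that("viability screen separates oxygen-dependent carbon sources", {
  toy <- toy_fixture()
  vs <- viability_screen(toy$model,
                         c(EX_glc = 10, EX_etoh = 20),
                         base_trace_medium(), "EX_o2")
  get <- function(src, reg) vs$growth_rate[vs$source == src & vs$regime == reg]
  expect_true(get("EX_glc", "aerobic") > get("EX_glc", "anaerobic"))
  expect_gt(get("EX_glc", "anaerobic"), LK_FLUX_TOL)
  # ethanol: NADH reoxidation needs oxygen; growth collapses >100-fold when
  # oxygen drops to the anaerobic bound and vanishes entirely without oxygen
  expect_lt(get("EX_etoh", "anaerobic"), 0.01 * get("EX_etoh", "aerobic"))
  m_noo2 <- apply_medium(toy$model,
    medium("etoh0", c(EX_h2o = 1000, EX_h = 1000, EX_co2 = 1000,
                      EX_nh4 = 1000, EX_etoh = 20)))
  expect_lt(fba(m_noo2)$objective, LK_FLUX_TOL)
  # carbon-free rows are non-viable; unknown exchange errors per row
  vs2 <- viability_screen(toy$model, c(EX_nope = 1), base_trace_medium(),
                          "EX_o2")
  expect_true(all(!is.na(vs2$error)))
})

test_that("biomass sensitivity: yield-limited scaling and toy ranking", {
  # single-precursor biomass: mu = uptake / c0, so +50% coefficient gives 2/3
  sp <- single_precursor_model(c0 = 1)
  bs <- biomass_sensitivity(sp, relative_perturbation = 0.5)
  expect_equal(bs$mu_base, 1)
  expect_equal(bs$mu_plus / bs$mu_base, 2 / 3, tolerance = 1e-8)
  expect_equal(bs$mu_minus / bs$mu_base, 2, tolerance = 1e-8)
  # toy: ATP cost dominates, nitrogen is non-limiting
  toy <- toy_fixture()
  bt <- biomass_sensitivity(toy$model, toy$media$minimal_glucose)
  expect_identical(bt$metabolite[1], "atp_c")
  expect_identical(bt$metabolite[nrow(bt)], "nh4_c")
  expect_lt(bt$sensitivity[nrow(bt)], 1e-8)
  expect_error(biomass_sensitivity(toy$model, toy$media$minimal_glucose,
                                   relative_perturbation = 1.5), "negative")
})

test_that("phenotypic phase plane: unconstrained corner aerobically, monotone decay, phases", {
  toy <- toy_fixture()
  aer <- toy$media$minimal_glucose
  pp <- phenotypic_phase_plane(toy$model, aer, "ETOHt", "ETACt", grid = 5)
  # aerobic optimum secretes neither product, so (0,0) is unconstrained
  expect_equal(pp$mu[1, 1], pp$mu_opt, tolerance = 1e-8)
  expect_identical(pp$phase[1, 1], 1L)
  # mu is non-increasing along each production axis (infeasible tail ignored)
  noninc <- function(v) all(diff(v[!is.na(v)]) < 1e-6)
  expect_true(all(apply(pp$mu, 2, noninc)))
  expect_true(all(apply(pp$mu, 1, noninc)))
  # semi-aerobic plane shows all three phases
  semi <- aer
  semi$uptake["EX_o2"] <- 3
  pp2 <- phenotypic_phase_plane(toy$model, semi, "ETOHt", "ETACt", grid = 6)
  expect_setequal(sort(unique(as.vector(pp2$phase))), c(1L, 2L, 3L))
})
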