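test_that("step update matches the closed-form exponential expressions", {
  # X' = X e^{mu dt}
  st <- step_update(X = 0.05, conc = c(S = 20), fluxes = c(S = 0),
                    dt = 0.5, mu = 0.2, molar_mass = c(S = 180))
  expect_equal(st$X, 0.05 * exp(0.1), tolerance = 1e-12)
  expect_equal(unname(st$conc["S"]), 20)          # zero flux: fixed point
  # mu = 0 limit: dS = v * (M/1000) * X * dt
  st2 <- step_update(X = 1, conc = c(S = 10), fluxes = c(S = -1),
                     dt = 1, mu = 0, molar_mass = c(S = 180))
  expect_equal(unname(st2$conc["S"]), 10 - 0.180, tolerance = 1e-12)
  # uptake depletes, secretion accumulates, with the X integral weight
  st3 <- step_update(X = 2, conc = c(P = 0), fluxes = c(P = 3),
                     dt = 0.5, mu = 0.2, molar_mass = c(P = 46.068))
  xint <- 2 * (exp(0.1) - 1) / 0.2
  expect_equal(unname(st3$conc["P"]), 3 * 46.068 / 1000 * xint,
               tolerance = 1e-12)
  # overshoot is clamped at zero and reported
  st4 <- step_update(X = 10, conc = c(S = 0.001), fluxes = c(S = -10),
                     dt = 1, mu = 0, molar_mass = c(S = 180))
  expect_equal(unname(st4$conc["S"]), 0)
  expect_identical(st4$clamped, "S")
})

test_that("availability bound caps uptake by the pool and vanishes without biomass", {
  expect_equal(availability_bound(1e6, 1, 0.5, 180, 10), 10)  # huge pool
  # pool exactly one step of draw at the kinetic bound returns the bound
  pool <- 10 * 180 / 1000 * 2 * 0.5     # v*M/1000*X*dt
  expect_equal(availability_bound(pool, 2, 0.5, 180, 10), 10, tolerance = 1e-12)
  expect_equal(availability_bound(0, 1, 0.5, 180, 10), 0)
  expect_equal(availability_bound(5, 0, 0.5, 180, 10), 0)
})

toy_dfba_params <- function(...) {
  dfba_params("EX_glc", substrate_mass = 180.156, o2_exchange = "EX_o2",
              products = c(EX_etoh = 46.068, EX_ac = 60.052,
                           EX_etac = 88.106, EX_co2 = 44.009), ...)
}

test_that("aerobic batch: biomass only, substrate exhausted, carbon conserved", {
  toy <- toy_fixture()
  tr <- simulate_batch(toy$model, toy_dfba_params(o2_uptake = 1000),
                       base_trace_medium())
  n <- nrow(tr)
  expect_equal(tr$time[n], 50)
  expect_lt(tr$EX_glc[n], 1e-6)                    # 20 g/L consumed
  expect_lt(max(tr$EX_etoh), 0.05)                 # no fermentation products
  expect_lt(max(tr$EX_etac), 0.05)
  expect_gt(tr$biomass[n], 5)                      # substantial growth
  expect_true(all(diff(tr$biomass) > -1e-9))       # X non-decreasing
  expect_true(all(tr[, c("EX_glc", "EX_etoh", "EX_ac", "EX_etac")] > -1e-12))
  expect_lt(trajectory_carbon_error(tr, toy_fixture()$truth$biomass_carbon),
            0.01)
})

test_that("oxygen-limited batch shows ethanol overflow and diauxic re-consumption", {
  toy <- toy_fixture()
  p <- toy_dfba_params(o2_uptake = 0.25, substrate_uptake = 10,
                       initial_biomass = 0.5)
  tr <- simulate_batch(toy$model, p, base_trace_medium())
  exh <- which(tr$EX_glc < 1e-9)[1]
  expect_false(is.na(exh))                         # glucose runs out
  peak <- which.max(tr$EX_etoh)
  expect_gt(tr$EX_etoh[peak], 5)                   # ethanol accumulates
  expect_gte(peak, exh - 1)                        # peak at exhaustion
  expect_lt(tr$EX_etoh[nrow(tr)], tr$EX_etoh[peak] - 0.1)  # then re-consumed
  expect_lt(max(tr$EX_etac), 1e-6)                 # no ester without acetate flux
  expect_lt(trajectory_carbon_error(tr, toy$truth$biomass_carbon), 0.01)
})

test_that("halving the sampling interval changes final biomass by under 2%", {
  toy <- toy_fixture()
  tr1 <- simulate_batch(toy$model, toy_dfba_params(dt = 0.5), base_trace_medium())
  tr2 <- simulate_batch(toy$model, toy_dfba_params(dt = 0.25), base_trace_medium())
  x1 <- tr1$biomass[nrow(tr1)]
  x2 <- tr2$biomass[nrow(tr2)]
  expect_lt(abs(x1 - x2) / x2, 0.02)
})

test_that("a culture that cannot grow is flagged stationary and conserves all pools", {
  toy <- toy_fixture()
  # no nitrogen: growth is impossible from the first interval
  tr <- simulate_batch(toy$model,
                       toy_dfba_params(total_time = 5),
                       medium("no_n", c(EX_h2o = 1000, EX_h = 1000,
                                        EX_co2 = 1000)))
  expect_true(all(abs(tr$biomass - tr$biomass[1]) < 1e-9))
  expect_true(all(abs(tr$EX_glc - tr$EX_glc[1]) < 1e-9))
  expect_true(all(tr$mu < 1e-9))
})

test_that("substrate depletion time matches the closed-form batch solution", {
  # single uptake-limited substrate: dX/dt = mu X with constant mu until S
  # runs out; S(t) integrates the same exponential, so depletion happens at
  # t* = ln(1 + S0 * mu / (Y' X0)) / mu with Y' = v M/1000
  toy <- toy_fixture()
  p <- toy_dfba_params(o2_uptake = 1000)
  tr <- simulate_batch(toy$model, p, base_trace_medium())
  mu <- toy$truth$aerobic_mu(p$substrate_uptake)
  draw <- p$substrate_uptake * p$substrate_mass / 1000
  t_star <- log(1 + p$initial_substrate * mu / (draw * p$initial_biomass)) / mu
  t_obs <- tr$time[which(tr$EX_glc < 1e-9)[1]]
  expect_lt(abs(t_obs - t_star), p$dt + 1e-9)
})
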