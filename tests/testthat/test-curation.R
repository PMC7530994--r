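test_that("balance checker agrees with a per-element summation oracle on random reactions", {
  set.seed(303)
  pool <- data.frame(
    id = paste0("m", 1:8), name = paste0("m", 1:8), compartment = "c",
    formula = c("C6H12O6", "C2H6O", "CO2", "H2O", "C3H6O3", "O2", "C2H4O2", "H"),
    charge = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  for (i in 1:100) {
    k <- sample(3:5, 1)
    mets <- sample(pool$id, k)
    coefs <- sample(c(-3:-1, 1:3), k, replace = TRUE)
    stoich <- list(RX = stats::setNames(as.numeric(coefs), mets),
                   BIO = c(m1 = -1))
    rxns <- data.frame(id = c("RX", "BIO"), name = c("RX", "BIO"), lb = 0,
                       ub = 1000, gpr = "", subsystem = "", confidence = NA_integer_)
    m <- metabolic_model("bal", c(c = "c"), pool, rxns, stoich, "BIO")
    rep <- check_mass_charge_balance(m)
    got <- rep$status[rep$reaction == "RX"] == "balanced"
    expect_identical(got, balance_oracle(m, "RX"), label = paste("trial", i))
  }
})

test_that("worked balances: fermentation stoichiometry, exemptions, R-moiety, missing formula", {
  mets <- data.frame(
    id = c("glc", "etoh", "co2", "acyl_a", "acyl_b", "x", "noform"),
    name = c("glucose", "ethanol", "CO2", "acyl donor", "acyl product", "x", "y"),
    compartment = "c",
    formula = c("C6H12O6", "C2H6O", "CO2", "C2H3OR", "C2H3OR", "C2H3O", NA),
    charge = c(0L, 0L, 0L, 0L, 0L, 0L, NA_integer_))
  stoich <- list(
    FERM = c(glc = -1, etoh = 2, co2 = 2),
    ACYL = c(acyl_a = -1, x = -0, acyl_b = 1),       # R conserved: a -> b
    BADFERM = c(glc = -1, etoh = 2, co2 = 1),
    NOF = c(noform = -1, co2 = 1),
    EX_glc = c(glc = -1),
    BIO = c(glc = -1))
  stoich$ACYL <- c(acyl_a = -1, acyl_b = 1)
  rxns <- data.frame(id = names(stoich), name = names(stoich), lb = 0,
                     ub = 1000, gpr = "", subsystem = "", confidence = NA_integer_)
  m <- metabolic_model("worked", c(c = "c"), mets, rxns, stoich, "BIO")
  rep <- check_mass_charge_balance(m)
  status <- stats::setNames(rep$status, rep$reaction)
  expect_identical(unname(status["FERM"]), "balanced")   # C 6=4+2, H 12=12, O 6=2+4
  expect_identical(unname(status["ACYL"]), "balanced")   # R carried through
  expect_identical(unname(status["BADFERM"]), "unbalanced")
  expect_identical(unname(status["NOF"]), "uncheckable")
  expect_identical(unname(status["EX_glc"]), "exempt")
  expect_identical(unname(status["BIO"]), "exempt")      # biomass
})

test_that("reversibility rules constrain ATP/O2/NAD(P)H reactions and log changes", {
  toy <- toy_fixture()
  m <- toy$model
  # free all internal reactions so the rules have something to do
  internal <- setdiff(m$reactions$id, c(exchange_reactions(m), m$biomass))
  m$reactions$lb[m$reactions$id %in% internal] <- -LK_BIG_BOUND
  species <- list(atp = "atp_c", o2 = c("o2_c", "o2_e"),
                  nadh = "nadh_c", nadph = character())
  out <- assign_reversibility(m, species)
  lb <- stats::setNames(out$model$reactions$lb, out$model$reactions$id)
  # ATP as reactant
  expect_equal(unname(lb["LACt"]), 0)
  expect_identical(out$log$rule[out$log$reaction == "LACt"], "atp_reactant")
  # NADH involvement
  expect_equal(unname(lb["ADH"]), 0)
  # no flagged species, no template: untouched
  expect_equal(unname(lb["GALE"]), -LK_BIG_BOUND)
  expect_equal(unname(lb["ETOHt"]), -LK_BIG_BOUND)
  # change log covers exactly the rule matches
  match_n <- sum(vapply(internal, function(rid) {
    st <- m$stoichiometry[[rid]]
    any(names(st) == "atp_c" & st < 0) ||
      any(names(st) %in% c("o2_c", "o2_e") & st > 0) ||
      any(names(st) == "nadh_c")
  }, logical(1)))
  expect_equal(nrow(out$log), match_n)
  # idempotence
  out2 <- assign_reversibility(out$model, species)
  expect_equal(out2$model$reactions$lb, out$model$reactions$lb)
  expect_equal(nrow(out2$log), 0)
  # template entries win over rules
  tmpl <- data.frame(reaction = "ADH", lb = -LK_BIG_BOUND, ub = LK_BIG_BOUND)
  out3 <- assign_reversibility(m, species, template_map = tmpl)
  expect_equal(out3$model$reactions$lb[out3$model$reactions$id == "ADH"],
               -LK_BIG_BOUND)
  # absent rule species is a configuration error
  expect_error(assign_reversibility(m, list(atp = "nope_c", o2 = "o2_c",
                                            nadh = "nadh_c")),
               "absent from model")
})

test_that("blocked reactions match brute-force FVA on micro fixtures and toy truth", {
  cd <- chain_deadend_model()
  got <- find_blocked_reactions(cd)
  bf <- brute_fva(cd)
  expect_setequal(got, bf$reaction[abs(bf$min) < 1e-6 & abs(bf$max) < 1e-6])
  expect_true("R_AD" %in% got)        # dead-end metabolite blocks its producer
  # fully connected chain: nothing blocked
  pb <- parallel_branch_model()
  expect_length(find_blocked_reactions(pb), 0)
  # toy ground truth under minimal glucose
  toy <- toy_fixture()
  expect_setequal(find_blocked_reactions(toy$model, toy$media$minimal_glucose),
                  toy$truth$blocked_minimal_glucose)
  # a reversed intermediate step blocks the downstream chain
  cd2 <- cd
  cd2$stoichiometry$R_AB <- c(A = 1, B = -1)    # direction flipped
  expect_true(all(c("R_AB", "EX_B") %in% find_blocked_reactions(cd2)))
})

test_that("biomass precursor producibility flags exactly the gaps", {
  toy <- toy_fixture()
  pc <- check_biomass_precursors(toy$model, toy$media$minimal_glucose)
  expect_true(all(pc$producible))
  # deleting the nitrogen supply flags exactly the ammonium precursor
  m2 <- toy$model
  m2$reactions$ub[m2$reactions$id == "NH4t"] <- 0
  pc2 <- check_biomass_precursors(m2, toy$media$minimal_glucose)
  expect_identical(pc2$metabolite[!pc2$producible], "nh4_c")
  # a precursor supplied directly by the medium is producible
  m3 <- m2
  med <- toy$media$minimal_glucose
  pc3 <- check_biomass_precursors(toy$model, med)  # NH4t intact, supplied
  expect_true(pc3$producible[pc3$metabolite == "nh4_c"])
})

test_that("confidence scores follow the GPR x flux rule", {
  toy <- toy_fixture()
  sol <- fba(toy$model, toy$media$minimal_glucose)
  m <- assign_confidence(toy$model, sol)
  conf <- stats::setNames(m$reactions$confidence, m$reactions$id)
  expect_equal(unname(conf["GLYC"]), 4L)     # GPR + flux
  expect_equal(unname(conf["GALE"]), 2L)     # GPR, no flux on glucose
  expect_equal(unname(conf["NH4t"]), 3L)     # flux, no GPR
  expect_equal(unname(conf["UREAt"]), 1L)    # neither
  expect_equal(unname(conf["EX_glc"]), 4L)   # exchange required for growth
})

test_that("pathway insertion preserves invariants, rejects collisions, flips uracil feasibility", {
  toy0 <- make_toy_model(toy_model_config(include_urc = FALSE))
  m0 <- toy0$model
  ura_med <- medium("uracil_n", c(EX_h2o = 1000, EX_h = 1000, EX_co2 = 1000,
                                  EX_glc = 10, EX_o2 = 1000, EX_ura = 1000))
  # without the pathway there is no nitrogen source: no growth
  no_n <- medium("no_n", c(EX_h2o = 1000, EX_h = 1000, EX_co2 = 1000,
                           EX_glc = 10, EX_o2 = 1000))
  expect_lt(fba(m0, no_n)$objective, LK_FLUX_TOL)
  m1 <- add_pathway(m0, urc_pathway_spec())
  expect_silent(validate_model(m1))
  expect_gt(fba(m1, ura_med)$objective, 0.1)
  # duplicate insertion collides
  expect_error(add_pathway(m1, urc_pathway_spec()), "collision")
  # optima of media not touching the new species are unchanged
  glc_med <- toy0$media$minimal_glucose
  expect_equal(fba(m1, glc_med)$objective, fba(m0, glc_med)$objective,
               tolerance = 1e-9)
})
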