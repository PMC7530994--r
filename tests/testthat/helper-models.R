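# Shared micro-fixtures, built in code. The full toy model comes from
# make_toy_model(); these are minimal hand-built networks for targeted
# checks.

# one cached toy model per suite run (construction is cheap but repeated)
.toy_cache <- new.env(parent = emptyenv())
toy_fixture <- function() {
  if (is.null(.toy_cache$toy)) .toy_cache$toy <- make_toy_model()
  .toy_cache$toy
}

# 3-reaction chain with a dead-end side product:
# EX_A -> A -> B (exported); A -> D (dead end, no consumer/exporter)
chain_deadend_model <- function() {
  mets <- data.frame(id = c("A", "B", "D"), name = c("A", "B", "D"),
                     compartment = "c", formula = NA_character_,
                     charge = NA_integer_)
  eqs <- list(EX_A = "A ->", EX_B = "B ->", R_AB = "A -> B", R_AD = "A -> D")
  rxns <- data.frame(id = names(eqs), name = names(eqs),
                     lb = c(-5, 0, 0, 0), ub = 1000, gpr = "",
                     subsystem = "core", confidence = NA_integer_)
  metabolic_model("chain_deadend", c(c = "c"), mets, rxns,
                  lapply(eqs, function(s) lkcbm:::.parse_eq(s)$stoich), "EX_B")
}

# two equivalent parallel branches feeding one demand:
# EX_A -> A; A -> B via R1 or R2; B -> (demand, bound 1)
parallel_branch_model <- function() {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c",
                     formula = NA_character_, charge = NA_integer_)
  eqs <- list(EX_A = "A ->", R1 = "A -> B", R2 = "A -> B", DM_B = "B ->")
  rxns <- data.frame(id = names(eqs), name = names(eqs),
                     lb = c(-1000, 0, 0, 0), ub = c(1000, 1000, 1000, 1),
                     gpr = c("", "g1", "g2", ""), subsystem = "core",
                     confidence = NA_integer_)
  metabolic_model("parallel", c(c = "c"), mets, rxns,
                  lapply(eqs, function(s) lkcbm:::.parse_eq(s)$stoich), "DM_B")
}

# single-precursor biomass: EX_P -> P (uptake 1); biomass: c0 * P ->
# growth is yield-limited: mu = uptake / c0
single_precursor_model <- function(c0 = 1) {
  mets <- data.frame(id = "P", name = "P", compartment = "c",
                     formula = NA_character_, charge = NA_integer_)
  stoich <- list(EX_P = c(P = -1), BIO = c(P = -c0))
  rxns <- data.frame(id = c("EX_P", "BIO"), name = c("EX_P", "BIO"),
                     lb = c(-1, 0), ub = 1000, gpr = "", subsystem = "core",
                     confidence = NA_integer_)
  metabolic_model("single_precursor", c(c = "c"), mets, rxns, stoich, "BIO")
}

# branch-choice network for MOMA: demand of 1 satisfied by v1 or v2
moma_branch_model <- function() parallel_branch_model()

base_trace_medium <- function() {
  medium("base", c(EX_h2o = 1000, EX_h = 1000, EX_co2 = 1000, EX_nh4 = 1000))
}

# total-carbon bookkeeping over a toy batch trajectory
trajectory_carbon_error <- function(tr, biomass_carbon) {
  n <- nrow(tr)
  dmmol <- function(col, mw) (tr[[col]][n] - tr[[col]][1]) * 1000 / mw
  consumed <- -dmmol("EX_glc", 180.156) * 6
  produced <- (tr$biomass[n] - tr$biomass[1]) * biomass_carbon +
    dmmol("EX_etoh", 46.068) * 2 + dmmol("EX_ac", 60.052) * 2 +
    dmmol("EX_etac", 88.106) * 4 + dmmol("EX_co2", 44.009) * 1
  abs(consumed - produced) / consumed
}
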