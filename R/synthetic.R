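# Seeded synthetic-data generators. The toy model is a ~45-reaction,
# two-compartment yeast-like network built around the physiology the
# pipeline is meant to interrogate:
#
#  * lumped glycolysis, a pyruvate-oxidizing respiratory branch (TCA lump +
#    oxidative phosphorylation) and a fermentative branch (pyruvate
#    decarboxylase + alcohol dehydrogenase), so respiration yields far more
#    ATP per glucose than fermentation and growth is ATP-limited — oxygen
#    limitation reproduces the respiro-fermentative (weak Crabtree) switch;
#  * an ethyl acetate branch: aldehyde dehydrogenase supplies acetate, an
#    alcohol acetyltransferase (AAT) condenses ethanol + acetate, and a
#    transporter secretes the ester — producible only when both precursors
#    carry flux, hence never in the anaerobic optimum;
#  * an optional uracil catabolism (URC) branch — uracil -> urea +
#    3-hydroxypropionate, urea -> 2 ammonium + CO2 — that lets uracil serve
#    as sole nitrogen source;
#  * alternative carbon routes (galactose, maltose, ethanol assimilation via
#    the reversible decarboxylase/dehydrogenase pair, so ethanol growth
#    needs oxygen to reoxidize NADH);
#  * a lactate "decoy" branch (dehydrogenase + ATP-coupled exporter) that is
#    never needed for growth: its ATP-coupled export keeps the fermentative
#    optimum uniquely ethanol and gives expression-driven extraction a
#    removable target;
#  * GPRs with single genes, complexes (AND) and isozyme pairs (OR).
#
# All real metabolites carry true molecular formulas, so internal reactions
# are elementally balanced and mass yields are meaningful; the lumped
# cofactor pairs (ATP/ADP/Pi as P/X pseudo-elements, NAD/NADH as Y/H) are
# balanced by construction. Charges are uniformly zero in the toy.
#
# Ground truth shipped with the model is derived analytically from the ATP
# stoichiometry: a fully respired glucose yields 28 ATP (2 glycolytic + 2
# substrate-level + 24 oxidative from 12 NADH at P/O = 2) and a fermented
# glucose 2 ATP, so with biomass costs of a glucose skeletons and e ATP per
# gdw the aerobic optimum is mu = 28 g / (e + 28 a) and the oxygen-limited
# optimum (uptake w) is mu = (2 g + 13 w / 3) / (e + 2 a).

#' Toy model configuration
#'
#' @param include_urc include the uracil catabolism branch.
#' @param include_ethyl_acetate include the AAT ester branch.
#' @param n_isozyme_pairs 0, 1 or 2 isozyme (OR) pairs: alcohol
#'   dehydrogenase and the respiratory chain.
#' @param biomass_glc,biomass_nh4,biomass_atp biomass drain coefficients
#'   (mmol per gdw): glucose carbon skeletons, ammonium, ATP. Defaults give
#'   mu = 0.205/h at a glucose uptake of 2.28 mmol/gdw/h (a realistic
#'   aerobic yeast yield of ~0.5 g/g).
#' @return a `toy_model_config` list.
#' @export
toy_model_config <- function(include_urc = TRUE, include_ethyl_acetate = TRUE,
                             n_isozyme_pairs = 2,
                             biomass_glc = 6.5, biomass_nh4 = 1,
                             biomass_atp = 130) {
  stopifnot(n_isozyme_pairs %in% 0:2, biomass_glc > 0, biomass_nh4 > 0,
            biomass_atp > 0)
  structure(list(include_urc = include_urc,
                 include_ethyl_acetate = include_ethyl_acetate,
                 n_isozyme_pairs = n_isozyme_pairs,
                 biomass_glc = biomass_glc, biomass_nh4 = biomass_nh4,
                 biomass_atp = biomass_atp),
            class = "toy_model_config")
}

# "a + 2 b -> c" / "a <-> b" equation parser for compact network definitions
.parse_eq <- function(eq) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (rev) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L && grepl("->", eq, fixed = TRUE))
    sides <- c(sides, "")   # strsplit drops the trailing empty product side
  if (length(sides) != 2L) stop("malformed equation: ", eq)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    out <- numeric()
    for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1]])) {
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 2L) {
        out[parts[2]] <- (if (parts[2] %in% names(out)) out[[parts[2]]] else 0) +
          sign * as.numeric(parts[1])
      } else {
        out[parts[1]] <- (if (parts[1] %in% names(out)) out[[parts[1]]] else 0) + sign
      }
    }
    out
  }
  st <- parse_side(sides[1], -1)
  pr <- parse_side(sides[2], 1)
  for (metab in names(pr))
    st[metab] <- (if (metab %in% names(st)) st[[metab]] else 0) + pr[[metab]]
  list(stoich = st[abs(st) > 0], reversible = rev)
}

#' Generate the toy yeast-like metabolic model
#'
#' @param config a [toy_model_config()].
#' @param seed unused by the (fully deterministic) network construction;
#'   kept so all generators share one signature.
#' @return list with `model` (a `metabolic_model`), `media` (named list of
#'   [medium()] presets: minimal media per carbon source, a rich medium, and
#'   ammonium-only / uracil-only nitrogen contexts), and `truth` — ground
#'   truth known by construction: `aerobic_mu(g)` and
#'   `anaerobic_mu(g, o2)` closed forms, `essential_minimal_glucose`,
#'   `blocked_minimal_glucose`, `decoy_reactions`, `urc_reactions`,
#'   `biomass_carbon` (mmol C per gdw) and `molar_mass` (named, g/mol).
#' @export
make_toy_model <- function(config = toy_model_config(), seed = 1L) {
  a <- config$biomass_glc; e_atp <- config$biomass_atp
  mets <- list(
    c("glc_e",  "D-glucose",          "e", "C6H12O6"),
    c("gal_e",  "D-galactose",        "e", "C6H12O6"),
    c("malt_e", "maltose",            "e", "C12H22O11"),
    c("etoh_e", "ethanol",            "e", "C2H6O"),
    c("ac_e",   "acetate",            "e", "C2H4O2"),
    c("lac_e",  "lactate",            "e", "C3H6O3"),
    c("o2_e",   "oxygen",             "e", "O2"),
    c("co2_e",  "carbon dioxide",     "e", "CO2"),
    c("h2o_e",  "water",              "e", "H2O"),
    c("h_e",    "proton",             "e", "H"),
    c("nh4_e",  "ammonium",           "e", "H4N"),
    c("glc_c",  "D-glucose",          "c", "C6H12O6"),
    c("gal_c",  "D-galactose",        "c", "C6H12O6"),
    c("malt_c", "maltose",            "c", "C12H22O11"),
    c("pyr_c",  "pyruvate",           "c", "C3H4O3"),
    c("acald_c","acetaldehyde",       "c", "C2H4O"),
    c("etoh_c", "ethanol",            "c", "C2H6O"),
    c("ac_c",   "acetate",            "c", "C2H4O2"),
    c("lac_c",  "lactate",            "c", "C3H6O3"),
    c("o2_c",   "oxygen",             "c", "O2"),
    c("co2_c",  "carbon dioxide",     "c", "CO2"),
    c("h2o_c",  "water",              "c", "H2O"),
    c("h_c",    "proton",             "c", "H"),
    c("nh4_c",  "ammonium",           "c", "H4N"),
    c("atp_c",  "ATP (lumped)",       "c", "P3X"),
    c("adp_c",  "ADP (lumped)",       "c", "P2X"),
    c("pi_c",   "phosphate (lumped)", "c", "P"),
    c("nad_c",  "NAD+ (lumped)",      "c", "Y"),
    c("nadh_c", "NADH (lumped)",      "c", "HY"))
  if (config$include_ethyl_acetate)
    mets <- c(mets, list(c("etac_e", "ethyl acetate", "e", "C4H8O2"),
                         c("etac_c", "ethyl acetate", "c", "C4H8O2")))
  if (config$include_urc)
    mets <- c(mets, list(c("ura_e",  "uracil",             "e", "C4H4N2O2"),
                         c("ura_c",  "uracil",             "c", "C4H4N2O2"),
                         c("urea_e", "urea",               "e", "CH4N2O"),
                         c("urea_c", "urea",               "c", "CH4N2O"),
                         c("hpp_e",  "3-hydroxypropionate","e", "C3H6O3"),
                         c("hpp_c",  "3-hydroxypropionate","c", "C3H6O3")))
  met_df <- data.frame(id = vapply(mets, `[`, "", 1),
                       name = vapply(mets, `[`, "", 2),
                       compartment = vapply(mets, `[`, "", 3),
                       formula = vapply(mets, `[`, "", 4),
                       charge = 0L)

  adh_gpr <- if (config$n_isozyme_pairs >= 1) "adh1 or adh2" else "adh1"
  etc_gpr <- if (config$n_isozyme_pairs >= 2) "etc1 or etc2" else "etc1"
  bio_eq <- sprintf("%g glc_c + %g nh4_c + %g atp_c -> %g adp_c + %g pi_c",
                    a, config$biomass_nh4, e_atp, e_atp, e_atp)
  rx <- list(
    # id, name, equation, irreversible?, gpr, subsystem
    list("EX_glc",  "glucose exchange",   "glc_e ->",  TRUE, "", "exchange"),
    list("EX_gal",  "galactose exchange", "gal_e ->",  TRUE, "", "exchange"),
    list("EX_malt", "maltose exchange",   "malt_e ->", TRUE, "", "exchange"),
    list("EX_etoh", "ethanol exchange",   "etoh_e ->", TRUE, "", "exchange"),
    list("EX_ac",   "acetate exchange",   "ac_e ->",   TRUE, "", "exchange"),
    list("EX_lac",  "lactate exchange",   "lac_e ->",  TRUE, "", "exchange"),
    list("EX_o2",   "oxygen exchange",    "o2_e ->",   TRUE, "", "exchange"),
    list("EX_co2",  "CO2 exchange",       "co2_e ->",  TRUE, "", "exchange"),
    list("EX_h2o",  "water exchange",     "h2o_e ->",  TRUE, "", "exchange"),
    list("EX_h",    "proton exchange",    "h_e ->",    TRUE, "", "exchange"),
    list("EX_nh4",  "ammonium exchange",  "nh4_e ->",  TRUE, "", "exchange"),
    list("GLCt",  "glucose uptake",     "glc_e -> glc_c",     TRUE,  "hxt1",  "transport"),
    list("GALt",  "galactose uptake",   "gal_e -> gal_c",     TRUE,  "gal2",  "transport"),
    list("MALTt", "maltose uptake",     "malt_e -> malt_c",   TRUE,  "mal11", "transport"),
    list("ETOHt", "ethanol diffusion",  "etoh_c <-> etoh_e",  FALSE, "",      "transport"),
    list("ACt",   "acetate transport",  "ac_c <-> ac_e",      FALSE, "",      "transport"),
    list("O2t",   "oxygen diffusion",   "o2_e <-> o2_c",      FALSE, "",      "transport"),
    list("CO2t",  "CO2 diffusion",      "co2_c <-> co2_e",    FALSE, "",      "transport"),
    list("H2Ot",  "water diffusion",    "h2o_c <-> h2o_e",    FALSE, "",      "transport"),
    list("Ht",    "proton diffusion",   "h_c <-> h_e",        FALSE, "",      "transport"),
    list("NH4t",  "ammonium uptake",    "nh4_e -> nh4_c",     TRUE,  "",      "transport"),
    list("GLYC", "glycolysis (lumped)",
         "glc_c + 2 nad_c + 2 adp_c + 2 pi_c -> 2 pyr_c + 2 nadh_c + 2 h_c + 2 atp_c",
         TRUE, "glk1 and pfk1", "glycolysis"),
    list("GNG", "gluconeogenesis (lumped)",
         "2 pyr_c + 2 nadh_c + 2 h_c + 4 atp_c -> glc_c + 2 nad_c + 4 adp_c + 4 pi_c",
         TRUE, "fbp1", "gluconeogenesis"),
    list("GALE", "galactose entry (Leloir, lumped)", "gal_c -> glc_c",
         TRUE, "gal10", "galactose metabolism"),
    list("MALTASE", "maltase", "malt_c + h2o_c -> 2 glc_c",
         TRUE, "mal1", "alternative carbon"),
    list("PDC", "pyruvate decarboxylase", "pyr_c <-> acald_c + co2_c",
         FALSE, "pdc1", "fermentation"),
    list("ADH", "alcohol dehydrogenase",
         "acald_c + nadh_c + h_c <-> etoh_c + nad_c",
         FALSE, adh_gpr, "fermentation"),
    list("ALD", "aldehyde dehydrogenase (acetate forming)",
         "acald_c + nad_c + h2o_c -> ac_c + nadh_c + h_c",
         TRUE, "ald6", "overflow metabolism"),
    list("TCA", "pyruvate oxidation (TCA, lumped)",
         "pyr_c + 3 h2o_c + 5 nad_c + adp_c + pi_c -> 3 co2_c + 5 nadh_c + 5 h_c + atp_c",
         TRUE, "tca1", "respiration"),
    list("ETC", "oxidative phosphorylation (P/O = 2)",
         "2 nadh_c + 2 h_c + o2_c + 4 adp_c + 4 pi_c -> 2 nad_c + 2 h2o_c + 4 atp_c",
         TRUE, etc_gpr, "respiration"),
    list("LDH", "lactate dehydrogenase (decoy branch)",
         "pyr_c + nadh_c + h_c -> lac_c + nad_c",
         TRUE, "ldh1", "overflow metabolism"),
    list("LACt", "lactate export (ATP-coupled, decoy branch)",
         "lac_c + atp_c -> lac_e + adp_c + pi_c",
         TRUE, "lct1", "overflow metabolism"),
    list("BIOMASS", "biomass synthesis", bio_eq, TRUE, "", "biomass"))
  if (config$include_ethyl_acetate)
    rx <- c(rx, list(
      list("EX_etac", "ethyl acetate exchange", "etac_e ->", TRUE, "", "exchange"),
      list("AAT", "alcohol acetyltransferase",
           "etoh_c + ac_c -> etac_c + h2o_c", TRUE, "aat1", "ethyl acetate"),
      list("ETACt", "ethyl acetate export", "etac_c -> etac_e", TRUE, "",
           "ethyl acetate")))
  if (config$include_urc)
    rx <- c(rx, list(
      list("EX_ura",  "uracil exchange", "ura_e ->",  TRUE, "", "exchange"),
      list("EX_urea", "urea exchange",   "urea_e ->", TRUE, "", "exchange"),
      list("EX_hpp",  "3-hydroxypropionate exchange", "hpp_e ->", TRUE, "",
           "exchange"),
      list("URAt",  "uracil permease", "ura_e -> ura_c",    TRUE,  "", "uracil degradation"),
      list("UREAt", "urea transport",  "urea_c <-> urea_e", FALSE, "", "uracil degradation"),
      list("HPPt",  "3-hydroxypropionate export", "hpp_c -> hpp_e", TRUE, "",
           "uracil degradation"),
      list("URC16", "uracil degradation (URC1/URC6, lumped)",
           "ura_c + 2 h2o_c + nadh_c + h_c -> urea_c + hpp_c + nad_c",
           TRUE, "urc1 and urc6", "uracil degradation"),
      list("URC35", "urea amidolyase (URC3/URC5)",
           "urea_c + h2o_c + 2 h_c + atp_c -> 2 nh4_c + co2_c + adp_c + pi_c",
           TRUE, "urc3 and urc5", "uracil degradation")))

  stoich <- list()
  rxn_df <- do.call(rbind, lapply(rx, function(r) {
    pe <- .parse_eq(r[[3]])
    stoich[[r[[1]]]] <<- pe$stoich
    rev <- pe$reversible && !r[[4]]
    data.frame(id = r[[1]], name = r[[2]],
               lb = if (rev) -LK_BIG_BOUND else 0, ub = LK_BIG_BOUND,
               gpr = r[[5]], subsystem = r[[6]], confidence = NA_integer_)
  }))
  model <- metabolic_model(
    id = "toy_weak_crabtree_yeast",
    compartments = c(e = "e", c = "c"),
    metabolites = met_df, reactions = rxn_df, stoichiometry = stoich,
    biomass = "BIOMASS")

  trace <- c(EX_h2o = LK_BIG_BOUND, EX_h = LK_BIG_BOUND,
             EX_co2 = LK_BIG_BOUND, EX_o2 = LK_BIG_BOUND)
  nh4 <- c(EX_nh4 = LK_BIG_BOUND)
  carbons <- c(EX_glc = 10, EX_gal = 10, EX_malt = 5, EX_etoh = 20)
  media <- list(
    minimal_glucose   = medium("minimal_glucose",   c(trace, nh4, EX_glc = 10)),
    minimal_galactose = medium("minimal_galactose", c(trace, nh4, EX_gal = 10)),
    minimal_maltose   = medium("minimal_maltose",   c(trace, nh4, EX_malt = 5)),
    minimal_ethanol   = medium("minimal_ethanol",   c(trace, nh4, EX_etoh = 20)),
    rich              = medium("rich", c(trace, nh4, carbons)))
  if (config$include_urc) {
    media$ammonium_n <- medium("ammonium_n", c(trace, nh4, EX_glc = 10))
    media$uracil_n <- medium("uracil_n",
                             c(trace, EX_ura = LK_BIG_BOUND, EX_glc = 10))
    media$rich <- medium("rich", c(trace, nh4, carbons, EX_ura = LK_BIG_BOUND))
  }

  # EX_h/Ht are blocked on glucose: hexose metabolism is proton-neutral by
  # construction (every NADH is born and consumed with its proton), so only
  # the urea amidolyase creates a net proton demand
  blocked <- c("EX_gal", "GALt", "GALE", "EX_malt", "MALTt", "MALTASE",
               "EX_h", "Ht")
  if (config$include_urc)
    blocked <- c(blocked, "EX_ura", "URAt", "URC16", "URC35",
                 "EX_urea", "UREAt", "EX_hpp", "HPPt")
  mm <- stats::setNames(
    vapply(model$metabolites$formula, formula_mass, numeric(1)),
    model$metabolites$id)
  truth <- list(
    aerobic_mu = function(g) 28 * g / (e_atp + 28 * a),
    anaerobic_mu = function(g, o2 = 0.25) (2 * g + 13 * o2 / 3) / (e_atp + 2 * a),
    essential_minimal_glucose = c("glk1", "hxt1", "pfk1"),
    # on ethanol: gluconeogenesis and the decarboxylase are the only route to
    # carbon skeletons; respiration is NOT essential because oxidizing ethanol
    # to secreted acetate still feeds NADH to the respiratory chain
    essential_minimal_ethanol = c("fbp1", "pdc1"),
    blocked_minimal_glucose = sort(blocked),
    decoy_reactions = c("LDH", "LACt"),
    urc_reactions = if (config$include_urc) c("URC16", "URC35") else character(),
    biomass_carbon = 6 * a,
    molar_mass = mm)
  list(model = model, media = media, truth = truth)
}

#' A 9-reaction single-compartment miniature for exact LP checks
#'
#' Pseudo-stoichiometric respiro-fermentative core (no formulas): glycolysis
#' 2 ATP + 2 NADH per glucose, respiration 10 ATP per pyruvate, NADH
#' oxidation 2 ATP per NADH, fermentation to ethanol, biomass 1 pyruvate +
#' 4 ATP. At glucose uptake `g` the analytic aerobic optimum is
#' `mu = 13 g / 7` (ATP-limited).
#'
#' @param glc_uptake glucose uptake bound (mmol/gdw/h).
#' @return list with `model` and `truth` (`mu_opt`).
#' @export
make_mini_model <- function(glc_uptake = 1) {
  mets <- data.frame(id = c("glc", "pyr", "atp", "nadh", "o2", "co2", "etoh"),
                     name = c("glucose", "pyruvate", "ATP", "NADH", "O2",
                              "CO2", "ethanol"),
                     compartment = "c", formula = NA_character_,
                     charge = NA_integer_)
  eqs <- list(
    EX_glc = "glc ->", EX_o2 = "o2 ->", EX_co2 = "co2 ->", EX_etoh = "etoh ->",
    GLYC = "glc -> 2 pyr + 2 atp + 2 nadh",
    RESP = "pyr + 2 o2 -> 3 co2 + 10 atp",
    NOX  = "2 nadh + o2 -> 4 atp",
    FERM = "pyr + nadh -> etoh + co2",
    BIO  = "pyr + 4 atp ->")
  stoich <- lapply(eqs, function(s) .parse_eq(s)$stoich)
  rxns <- data.frame(id = names(eqs), name = names(eqs),
                     lb = 0, ub = LK_BIG_BOUND, gpr = "", subsystem = "core",
                     confidence = NA_integer_)
  rxns$lb[rxns$id == "EX_glc"] <- -glc_uptake
  rxns$lb[rxns$id == "EX_o2"] <- -LK_BIG_BOUND
  model <- metabolic_model("mini_core", c(c = "c"), mets, rxns, stoich, "BIO")
  list(model = model, truth = list(mu_opt = 13 * glc_uptake / 7))
}

#' A chain-plus-cycle miniature for loopless FVA checks
#'
#' A linear pathway (uptake of A, conversion to B, export of B) with an
#' internal 3-reaction cycle A -> B -> C -> A bolted on. With the cycle
#' irreversible, plain FVA lets the cycle reactions run up to the futile
#' 1000-magnitude loop while loopless FVA pins them to the chain-only flux.
#'
#' @param uptake uptake bound of A.
#' @param reversible_cycle make the three cycle reactions reversible.
#' @return a `metabolic_model` (objective: export of B).
#' @export
make_loop_model <- function(uptake = 10, reversible_cycle = FALSE) {
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c", formula = NA_character_,
                     charge = NA_integer_)
  eqs <- list(EX_A = "A ->", EX_B = "B ->",
              R1 = "A -> B", R2 = "B -> C", R3 = "C -> A")
  stoich <- lapply(eqs, function(s) .parse_eq(s)$stoich)
  lb <- c(-uptake, 0, if (reversible_cycle) rep(-LK_BIG_BOUND, 3) else rep(0, 3))
  rxns <- data.frame(id = names(eqs), name = names(eqs),
                     lb = lb, ub = LK_BIG_BOUND, gpr = "", subsystem = "core",
                     confidence = NA_integer_)
  metabolic_model("loop_demo", c(c = "c"), mets, rxns, stoich, "EX_B")
}

#' Paired two-condition expression profiles for the toy model
#'
#' Emulates a two-condition nitrogen-source experiment (ammonium vs uracil
#' as sole nitrogen source). Baseline expression is log-normal around 10;
#' condition-specific gene sets are drawn log-normally around 1, far below
#' the 25th percentile of the scored-reaction distribution:
#'
#'  * ammonium condition: the URC genes and the lactate decoy branch are low
#'    (uracil catabolism silent, decoy silent);
#'  * uracil condition: the decoy branch plus the respiratory genes are low
#'    — the latter are flux-forced, so expression-driven extraction must
#'    keep them and the decoy branch is exactly what it removes.
#'
#' @param model the toy `metabolic_model`.
#' @param seed integer seed (profiles are bit-reproducible given it).
#' @return named list of two profiles, `ammonium` and `uracil`, each a list
#'   with `condition`, `values` (named over model genes) and `low_genes`.
#' @export
make_expression_profiles <- function(model, seed = 1L) {
  set.seed(seed)
  genes <- model$genes
  low_amm <- intersect(c("ldh1", "lct1", "urc1", "urc6", "urc3", "urc5"), genes)
  low_ura <- intersect(c("ldh1", "lct1", "tca1", "etc1", "etc2"), genes)
  draw <- function(low) {
    v <- stats::rlnorm(length(genes), meanlog = log(10), sdlog = 0.15)
    names(v) <- genes
    v[low] <- stats::rlnorm(length(low), meanlog = log(1), sdlog = 0.15)
    v
  }
  list(ammonium = list(condition = "ammonium", values = draw(low_amm),
                       low_genes = low_amm),
       uracil = list(condition = "uracil", values = draw(low_ura),
                     low_genes = low_ura))
}

#' Synthetic experimental condition table with known ground truth
#'
#' Samples glucose/oxygen uptake pairs across aerobic, semi-aerobic and
#' anaerobic regimes, computes the model's own predictions, and perturbs
#' them with multiplicative Gaussian noise to play the role of measurements.
#'
#' @param model the toy `metabolic_model`.
#' @param med base medium (nitrogen + trace), e.g. the generated
#'   `minimal_glucose`.
#' @param n_conditions number of rows.
#' @param noise_sd multiplicative noise standard deviation (0 = noiseless).
#' @param seed integer seed.
#' @return a condition table data.frame (see [run_condition_table()]) with
#'   `measured_mu`, `measured_rq` and attributes `true_mu`, `true_rq`.
#' @export
make_condition_table <- function(model, med, n_conditions = 8,
                                 noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  glc <- stats::runif(n_conditions, 1.5, 4)
  o2 <- sample(c(1000, 3, 0.25), n_conditions, replace = TRUE)
  tab <- data.frame(condition = paste0("cond", seq_len(n_conditions)),
                    substrate_exchange = "EX_glc",
                    substrate_uptake = glc, o2_uptake = o2)
  pred <- run_condition_table(model, tab, med, "EX_o2", "EX_co2")
  tab$measured_mu <- pred$predicted_mu *
    (1 + stats::rnorm(n_conditions, 0, noise_sd))
  tab$measured_rq <- pred$predicted_rq *
    (1 + stats::rnorm(n_conditions, 0, noise_sd))
  attr(tab, "true_mu") <- pred$predicted_mu
  attr(tab, "true_rq") <- pred$predicted_rq
  tab
}

#' Synthetic OD600 time course
#'
#' `OD(t) = od0 * exp(mu t) * (1 + eps_t)`, `eps_t ~ N(0, noise_sd)`; the
#' default grid mirrors a 2-hourly sampling cadence starting from an
#' inoculum diluted to OD 0.2.
#'
#' @param mu_true true specific growth rate (1/h), >= 0.
#' @param od0 initial OD600 (> 0).
#' @param t_grid sampling times (h).
#' @param noise_sd multiplicative noise sd.
#' @param seed integer seed.
#' @return data.frame with columns `time` and `od`.
#' @export
make_od_series <- function(mu_true, od0 = 0.2, t_grid = seq(0, 12, by = 2),
                           noise_sd = 0, seed = 1L) {
  stopifnot(mu_true >= 0, od0 > 0)
  set.seed(seed)
  od <- od0 * exp(mu_true * t_grid) * (1 + stats::rnorm(length(t_grid), 0, noise_sd))
  data.frame(time = t_grid, od = pmax(od, 1e-9))
}
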