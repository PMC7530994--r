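# Shipped pathway specifications: the uracil catabolism (URC) route and the
# ethyl acetate (AAT) branch, as insertable units matching the toy-model
# namespace. Inserting the URC spec into a toy model generated with
# include_urc = FALSE makes growth on uracil as the sole nitrogen source
# feasible; the definitions mirror the built-in branches of make_toy_model.

.pathway_met_df <- function(rows) {
  data.frame(id = vapply(rows, `[`, "", 1), name = vapply(rows, `[`, "", 2),
             compartment = vapply(rows, `[`, "", 3),
             formula = vapply(rows, `[`, "", 4), charge = 0L)
}

.pathway_rxn_df <- function(rows) {
  stoich <- list()
  df <- do.call(rbind, lapply(rows, function(r) {
    pe <- .parse_eq(r[[3]])
    stoich[[r[[1]]]] <<- pe$stoich
    data.frame(id = r[[1]], name = r[[2]],
               lb = if (pe$reversible) -LK_BIG_BOUND else 0,
               ub = LK_BIG_BOUND, gpr = r[[4]], subsystem = r[[5]],
               confidence = NA_integer_)
  }))
  list(df = df, stoich = stoich)
}

#' Uracil catabolism (URC) pathway specification
#'
#' Uracil is degraded to urea plus 3-hydroxypropionate (the URC1/URC6 lump),
#' and urea is hydrolysed by the ATP-dependent urea amidolyase (URC3/URC5)
#' to two ammonium and CO2, replenishing the nitrogen pool. Permeases for
#' uracil and urea and an exporter for 3-hydroxypropionate are included so
#' the intermediates can cross the membrane.
#'
#' @return a [pathway_spec()].
#' @export
urc_pathway_spec <- function() {
  mets <- .pathway_met_df(list(
    c("ura_e",  "uracil",              "e", "C4H4N2O2"),
    c("ura_c",  "uracil",              "c", "C4H4N2O2"),
    c("urea_e", "urea",                "e", "CH4N2O"),
    c("urea_c", "urea",                "c", "CH4N2O"),
    c("hpp_e",  "3-hydroxypropionate", "e", "C3H6O3"),
    c("hpp_c",  "3-hydroxypropionate", "c", "C3H6O3")))
  rr <- .pathway_rxn_df(list(
    list("EX_ura",  "uracil exchange", "ura_e ->", "", "exchange"),
    list("EX_urea", "urea exchange",   "urea_e ->", "", "exchange"),
    list("EX_hpp",  "3-hydroxypropionate exchange", "hpp_e ->", "", "exchange"),
    list("URAt",  "uracil permease", "ura_e -> ura_c", "", "uracil degradation"),
    list("UREAt", "urea transport",  "urea_c <-> urea_e", "", "uracil degradation"),
    list("HPPt",  "3-hydroxypropionate export", "hpp_c -> hpp_e", "",
         "uracil degradation"),
    list("URC16", "uracil degradation (URC1/URC6, lumped)",
         "ura_c + 2 h2o_c + nadh_c + h_c -> urea_c + hpp_c + nad_c",
         "urc1 and urc6", "uracil degradation"),
    list("URC35", "urea amidolyase (URC3/URC5)",
         "urea_c + h2o_c + 2 h_c + atp_c -> 2 nh4_c + co2_c + adp_c + pi_c",
         "urc3 and urc5", "uracil degradation")))
  pathway_spec("uracil catabolism (URC)", mets, rr$df, rr$stoich)
}

#' Ethyl acetate (AAT) pathway specification
#'
#' Alcohol acetyltransferase condenses ethanol and acetate into ethyl
#' acetate, which a (hypothetical) transporter secretes.
#'
#' @return a [pathway_spec()].
#' @export
ethyl_acetate_pathway_spec <- function() {
  mets <- .pathway_met_df(list(
    c("etac_e", "ethyl acetate", "e", "C4H8O2"),
    c("etac_c", "ethyl acetate", "c", "C4H8O2")))
  rr <- .pathway_rxn_df(list(
    list("EX_etac", "ethyl acetate exchange", "etac_e ->", "", "exchange"),
    list("AAT", "alcohol acetyltransferase",
         "etoh_c + ac_c -> etac_c + h2o_c", "aat1", "ethyl acetate"),
    list("ETACt", "ethyl acetate export", "etac_c -> etac_e", "",
         "ethyl acetate")))
  pathway_spec("ethyl acetate (AAT)", mets, rr$df, rr$stoich)
}
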