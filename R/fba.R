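# Flux balance analysis and the desk-scale physiology quantities derived
# from a flux solution (respiratory quotient, mass yields), plus the screens
# built directly on repeated FBA: carbon-source viability, biomass
# coefficient sensitivity and phenotypic phase planes.

#' Flux balance analysis
#'
#' Maximizes the flux of the objective reaction (by default the biomass
#' pseudo-reaction, whose flux is the specific growth rate in 1/h) subject to
#' steady-state mass balance `S v = 0` and the flux bounds, after applying
#' the medium.
#'
#' @param model a `metabolic_model`.
#' @param med optional [medium()] applied before solving.
#' @param objective reaction id to maximize (default: the biomass reaction).
#' @param maximize logical; set `FALSE` to minimize the objective flux.
#' @return an object of class `flux_solution`: list with `status`
#'   ("optimal"/"infeasible"/"unbounded"), `objective` (the optimal objective
#'   flux; `NA` unless optimal) and `fluxes` (named vector, mmol/gdw/h).
#' @export
fba <- function(model, med = NULL, objective = model$biomass, maximize = TRUE) {
  model <- apply_medium(model, med)
  .rxn_index(model, objective)
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(model$reactions$id == objective)
  sol <- solve_lp(obj, S, NULL, model$reactions$lb, model$reactions$ub,
                  maximize = maximize)
  fluxes <- NULL
  if (sol$status == "optimal") {
    fluxes <- sol$x
    names(fluxes) <- model$reactions$id
  }
  structure(list(status = sol$status,
                 objective = if (sol$status == "optimal") sol$objective else NA_real_,
                 objective_id = objective,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status, "\n")
  if (x$status == "optimal") {
    cat("  objective (", x$objective_id, "): ", signif(x$objective, 6), "\n", sep = "")
    nz <- x$fluxes[abs(x$fluxes) > LK_FLUX_TOL]
    cat("  active reactions:", length(nz), "of", length(x$fluxes), "\n")
  }
  invisible(x)
}

#' Respiratory quotient of a flux solution
#'
#' RQ = CO2 production flux / O2 uptake flux (magnitude): about 1 for fully
#' respiratory carbohydrate metabolism, above 1 under fermentative overflow.
#'
#' @param sol a `flux_solution`, or a named flux vector.
#' @param co2_exchange,o2_exchange ids of the CO2 and O2 exchange reactions.
#' @return dimensionless ratio.
#' @export
respiratory_quotient <- function(sol, co2_exchange, o2_exchange) {
  v <- if (inherits(sol, "flux_solution")) sol$fluxes else sol
  if (is.null(v)) stop("no flux vector (solution not optimal?)")
  o2_uptake <- -v[[o2_exchange]]
  if (!(o2_uptake > LK_FLUX_TOL))
    stop("respiratory quotient undefined: no oxygen uptake")
  v[[co2_exchange]] / o2_uptake
}

#' Mass yield of a product on a substrate (g/g)
#'
#' @param sol a `flux_solution` or named flux vector.
#' @param product_exchange,substrate_exchange exchange reaction ids.
#' @param product_mass,substrate_mass molar masses (g/mol).
#' @return yield in grams of product per gram of substrate consumed.
#' @export
product_yield <- function(sol, product_exchange, substrate_exchange,
                          product_mass, substrate_mass) {
  v <- if (inherits(sol, "flux_solution")) sol$fluxes else sol
  if (is.null(v)) stop("no flux vector (solution not optimal?)")
  uptake <- -v[[substrate_exchange]]
  if (!(uptake > LK_FLUX_TOL))
    stop("product yield undefined: no substrate uptake")
  (v[[product_exchange]] * product_mass) / (uptake * substrate_mass)
}

#' Carbon-source viability screen
#'
#' For each candidate carbon source and oxygen regime, builds a medium with
#' that source as the sole carbon supply on top of a carbon-free base medium,
#' runs FBA, and reports the growth rate and (optionally) its FVA range.
#' Aerobic O2 uptake is unconstrained at 1000 mmol/gdw/h; anaerobic is
#' limited to 0.25 mmol/gdw/h.
#'
#' @param model a `metabolic_model`.
#' @param carbon_sources data.frame with columns `exchange` (exchange id) and
#'   `uptake` (mmol/gdw/h), or a named numeric vector.
#' @param base_medium a [medium()] supplying everything except carbon and O2
#'   (nitrogen source, water, trace elements).
#' @param o2_exchange id of the O2 exchange reaction.
#' @param regimes subset of `c("aerobic", "anaerobic")`.
#' @param fva_range logical: also report min/max growth rate at optimality
#'   fraction 1 (degenerate unless alternate optima exist) — kept for
#'   symmetry with published growth-rate error bars, default off.
#' @return data.frame with columns `source`, `regime`, `growth_rate`,
#'   `viable` and `error` (NA unless the row failed).
#' @export
viability_screen <- function(model, carbon_sources, base_medium, o2_exchange,
                             regimes = c("aerobic", "anaerobic"),
                             fva_range = FALSE) {
  if (is.numeric(carbon_sources))
    carbon_sources <- data.frame(exchange = names(carbon_sources),
                                 uptake = as.numeric(carbon_sources))
  o2_by_regime <- c(aerobic = LK_BIG_BOUND, anaerobic = 0.25)
  rows <- list()
  for (k in seq_len(nrow(carbon_sources))) {
    for (reg in regimes) {
      row <- data.frame(source = carbon_sources$exchange[k], regime = reg,
                        growth_rate = NA_real_, mu_min = NA_real_,
                        mu_max = NA_real_, viable = NA, error = NA_character_)
      res <- tryCatch({
        up <- base_medium$uptake
        up[carbon_sources$exchange[k]] <- carbon_sources$uptake[k]
        up[o2_exchange] <- o2_by_regime[[reg]]
        med <- medium(paste0(base_medium$name, "+", carbon_sources$exchange[k],
                             "/", reg), up)
        m2 <- apply_medium(model, med)   # validates the exchange id
        sol <- fba(m2)
        mu <- if (sol$status == "optimal") sol$objective else 0
        row$growth_rate <- mu
        row$viable <- mu > LK_FLUX_TOL
        if (fva_range && sol$status == "optimal") {
          iv <- fva(m2, reactions = model$biomass, fraction_of_optimum = 1)
          row$mu_min <- iv$min; row$mu_max <- iv$max
        }
        row
      }, error = function(e) { row$error <- conditionMessage(e); row })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (!fva_range) out$mu_min <- out$mu_max <- NULL
  rownames(out) <- NULL
  out
}

#' Sensitivity of growth to biomass coefficients
#'
#' Perturbs each biomass precursor coefficient by a relative fraction (the
#' conventional screen uses +/-50%) and re-runs FBA; reports the resulting
#' growth rates and deltas. The model is never permanently modified.
#'
#' @param model a `metabolic_model`.
#' @param med optional [medium()].
#' @param relative_perturbation positive fraction (0.5 = +/-50%).
#' @return data.frame with one row per biomass substrate: `metabolite`,
#'   `coefficient`, `mu_base`, `mu_minus`, `mu_plus`, `delta_minus`,
#'   `delta_plus`, `sensitivity` (max |delta|).
#' @export
biomass_sensitivity <- function(model, med = NULL, relative_perturbation = 0.5) {
  if (relative_perturbation <= 0 || relative_perturbation >= 1)
    stop("relative_perturbation must be in (0, 1): a larger perturbation would ",
         "make some coefficient negative")
  model <- apply_medium(model, med)
  st <- model$stoichiometry[[model$biomass]]
  subs <- names(st)[st < 0]
  if (length(subs) == 0L) stop("biomass reaction has no substrates")
  base <- fba(model)
  if (base$status != "optimal") stop("baseline FBA not optimal")
  mu0 <- base$objective
  res <- lapply(subs, function(metab) {
    mus <- vapply(c(1 - relative_perturbation, 1 + relative_perturbation),
                  function(f) {
      m2 <- model
      m2$stoichiometry[[m2$biomass]][metab] <- st[metab] * f
      s <- fba(m2)
      if (s$status == "optimal") s$objective else 0
    }, numeric(1))
    data.frame(metabolite = metab, coefficient = -st[[metab]],
               mu_base = mu0, mu_minus = mus[1], mu_plus = mus[2],
               delta_minus = mus[1] - mu0, delta_plus = mus[2] - mu0,
               sensitivity = max(abs(mus - mu0)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(-out$sensitivity), ]
}

#' Phenotypic phase plane
#'
#' Fixes the production fluxes of two reactions on a grid and maximizes
#' growth at each grid point. Phase 1 is the optimal-growth region (growth
#' within 99% of the unconstrained optimum), phase 2 the growth-penalized
#' region, phase 3 the infeasible / negligible-growth region.
#'
#' @param model a `metabolic_model`.
#' @param med optional [medium()].
#' @param rxn_a,rxn_b reaction ids whose fluxes span the plane.
#' @param grid number of grid points per axis.
#' @param max_a,max_b largest fixed flux per axis; defaults to each
#'   reaction's maximal attainable flux under the medium.
#' @return an object of class `phase_plane`: list with `a`, `b` (axis
#'   values), `mu` (matrix of growth rates), `phase` (integer matrix) and
#'   `mu_opt` (the unconstrained optimum).
#' @export
phenotypic_phase_plane <- function(model, med = NULL, rxn_a, rxn_b, grid = 10,
                                   max_a = NULL, max_b = NULL) {
  model <- apply_medium(model, med)
  .rxn_index(model, c(rxn_a, rxn_b))
  base <- fba(model)
  if (base$status != "optimal") stop("FBA infeasible under the given medium")
  mu_opt <- base$objective
  if (is.null(max_a))
    max_a <- fba(model, objective = rxn_a)$objective
  if (is.null(max_b))
    max_b <- fba(model, objective = rxn_b)$objective
  a_vals <- seq(0, max_a, length.out = grid)
  b_vals <- seq(0, max_b, length.out = grid)
  mu <- matrix(NA_real_, grid, grid)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      m2 <- set_bounds(model, rxn_a, lb = a_vals[i], ub = a_vals[i])
      m2 <- set_bounds(m2, rxn_b, lb = b_vals[j], ub = b_vals[j])
      s <- tryCatch(fba(m2), error = function(e) list(status = "error"))
      mu[i, j] <- if (identical(s$status, "optimal")) s$objective else NA_real_
    }
  }
  phase <- matrix(3L, grid, grid)
  ok <- !is.na(mu) & mu > LK_FLUX_TOL
  phase[ok & mu >= 0.99 * mu_opt] <- 1L
  phase[ok & mu < 0.99 * mu_opt] <- 2L
  structure(list(a = a_vals, b = b_vals, rxn_a = rxn_a, rxn_b = rxn_b,
                 mu = mu, phase = phase, mu_opt = mu_opt),
            class = "phase_plane")
}

#' @export
print.phase_plane <- function(x, ...) {
  cat("Phenotypic phase plane ", x$rxn_a, " x ", x$rxn_b, " (",
      length(x$a), "x", length(x$b), " grid)\n", sep = "")
  cat("  unconstrained optimum:", signif(x$mu_opt, 5), "\n")
  cat("  phase counts:", paste(names(table(x$phase)), table(x$phase),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.phase_plane <- function(x, ...) {
  graphics::image(x$a, x$b, x$mu, xlab = x$rxn_a, ylab = x$rxn_b,
                  main = "Phenotypic phase plane (growth rate)", ...)
  graphics::contour(x$a, x$b, x$phase, levels = c(1.5, 2.5), add = TRUE,
                    drawlabels = FALSE)
  invisible(x)
}
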