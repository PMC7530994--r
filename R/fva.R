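# Flux variability analysis, its loopless variant, and blocked-reaction
# detection.
#
# Loopless FVA excludes flux attributable to thermodynamically infeasible
# internal cycles. The implementation is exact: loop-capable reactions are
# the support of the nullspace of the internal (non-exchange) stoichiometric
# submatrix; for each admissible sign pattern over that set — admissibility
# meaning a Gibbs-energy-like potential G exists with N'G = 0 and sign(G_i)
# opposed to the pattern — a sign-restricted LP gives the reachable flux
# range, and the loopless interval is the union over admissible patterns.
# This enumerates exactly the branches the usual ll-FVA MILP would explore;
# with no loop-capable reactions it reduces to plain FVA (acyclic networks).

#' Flux variability analysis
#'
#' Per-reaction minimal and maximal flux subject to steady state, the flux
#' bounds, and the objective attaining at least `fraction_of_optimum` of its
#' FBA optimum.
#'
#' @param model a `metabolic_model`.
#' @param med optional [medium()].
#' @param objective objective reaction id (default biomass).
#' @param fraction_of_optimum number in \[0, 1\]; 1 restricts the flux space
#'   to the optimal face, 0 imposes no objective constraint.
#' @param reactions reaction ids to analyse (default all).
#' @return an object of class `flux_interval`: data.frame with columns
#'   `reaction`, `min`, `max`; attribute `fraction_of_optimum`.
#' @export
fva <- function(model, med = NULL, objective = model$biomass,
                fraction_of_optimum = 1, reactions = NULL) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  model <- apply_medium(model, med)
  if (is.null(reactions)) reactions <- model$reactions$id
  .rxn_index(model, reactions)
  if (fraction_of_optimum > 0) {
    base <- fba(model, objective = objective)
    if (base$status != "optimal")
      stop("FBA ", base$status, " under the given medium")
    i <- .rxn_index(model, objective)
    model$reactions$lb[i] <- max(model$reactions$lb[i],
                                 fraction_of_optimum * base$objective)
  }
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  res <- vapply(reactions, function(rid) {
    obj <- as.numeric(model$reactions$id == rid)
    lo <- solve_lp(obj, S, NULL, lb, ub, maximize = FALSE)
    hi <- solve_lp(obj, S, NULL, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem ", lo$status, " for reaction '", rid, "'")
    c(lo$objective, hi$objective)
  }, numeric(2))
  out <- data.frame(reaction = reactions, min = res[1, ], max = res[2, ])
  # forced reactions can show min > max by LP round-off; collapse the inversion
  inv <- out$min > out$max
  if (any(inv)) {
    if (any(out$min[inv] - out$max[inv] > 1e-6))
      stop("inconsistent FVA interval for: ",
           paste(out$reaction[inv][out$min[inv] - out$max[inv] > 1e-6],
                 collapse = ", "))
    mid <- (out$min[inv] + out$max[inv]) / 2
    out$min[inv] <- mid; out$max[inv] <- mid
  }
  rownames(out) <- NULL
  structure(out, fraction_of_optimum = fraction_of_optimum,
            class = c("flux_interval", "data.frame"))
}

# loop-capable reactions: support of the nullspace of S over internal columns
.loop_reactions <- function(model, tol = 1e-8) {
  internal <- setdiff(model$reactions$id, exchange_reactions(model))
  if (length(internal) == 0L) return(list(ids = character(), N = NULL))
  S <- stoichiometric_matrix(model)[, internal, drop = FALSE]
  sv <- svd(S, nu = 0)
  rk <- sum(sv$d > max(dim(S)) * max(sv$d, 0) * 1e-12)
  if (rk == ncol(S)) return(list(ids = character(), N = NULL))
  N <- sv$v[, (rk + 1):ncol(S), drop = FALSE]
  rownames(N) <- internal
  on <- rowSums(abs(N)) > tol
  list(ids = internal[on], N = N[on, , drop = FALSE])
}

# admissible sign patterns: exists G with N'G = 0 and G_i in [1,K] (pattern -1,
# i.e. reverse flux allowed) or [-K,-1] (pattern +1, forward flux allowed)
.admissible_patterns <- function(N, K = 1000) {
  k <- nrow(N)
  patterns <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
  ok <- apply(patterns, 1, function(sgn) {
    lbG <- ifelse(sgn > 0, -K, 1)
    ubG <- ifelse(sgn > 0, -1, K)
    f <- solve_lp(numeric(k), t(N), NULL, lbG, ubG, maximize = TRUE)
    f$status == "optimal"
  })
  patterns[ok, , drop = FALSE]
}

#' Loopless flux variability analysis
#'
#' As [fva()], but flux through thermodynamically infeasible internal cycles
#' is excluded. Intervals are always contained in the plain FVA intervals,
#' with equality on acyclic networks. Reactions that cannot participate in
#' any internal cycle keep their plain FVA interval.
#'
#' @inheritParams fva
#' @param max_loop_reactions cap on the number of loop-capable reactions (the
#'   enumeration is exponential in it); exceeded -> error telling the caller
#'   the intervals would be unresolved, never a silently wrong interval.
#' @return a `flux_interval` with attribute `loop_reactions`.
#' @export
loopless_fva <- function(model, med = NULL, objective = model$biomass,
                         fraction_of_optimum = 1, reactions = NULL,
                         max_loop_reactions = 12L) {
  plain <- fva(model, med, objective, fraction_of_optimum, reactions)
  model <- apply_medium(model, med)
  loops <- .loop_reactions(model)
  attr(plain, "loop_reactions") <- loops$ids
  if (length(loops$ids) == 0L) return(plain)
  if (length(loops$ids) > max_loop_reactions)
    stop(length(loops$ids), " loop-capable reactions exceed the enumeration ",
         "cap (", max_loop_reactions, "); intervals unresolved")
  patterns <- .admissible_patterns(loops$N)
  if (is.null(reactions)) reactions <- model$reactions$id
  if (fraction_of_optimum > 0) {
    base <- fba(model, objective = objective)
    i <- .rxn_index(model, objective)
    model$reactions$lb[i] <- max(model$reactions$lb[i],
                                 fraction_of_optimum * base$objective)
  }
  S <- stoichiometric_matrix(model)
  li <- match(loops$ids, model$reactions$id)
  target <- intersect(reactions, loops$ids)
  for (rid in target) {
    lo_best <- Inf; hi_best <- -Inf
    obj <- as.numeric(model$reactions$id == rid)
    for (p in seq_len(nrow(patterns))) {
      lb <- model$reactions$lb; ub <- model$reactions$ub
      sgn <- patterns[p, ]
      lb[li] <- ifelse(sgn > 0, pmax(lb[li], 0), lb[li])
      ub[li] <- ifelse(sgn > 0, ub[li], pmin(ub[li], 0))
      lo <- solve_lp(obj, S, NULL, lb, ub, maximize = FALSE)
      hi <- solve_lp(obj, S, NULL, lb, ub, maximize = TRUE)
      if (lo$status == "optimal") lo_best <- min(lo_best, lo$objective)
      if (hi$status == "optimal") hi_best <- max(hi_best, hi$objective)
    }
    if (!is.finite(lo_best) || !is.finite(hi_best))
      stop("no loopless flux pattern feasible for reaction '", rid, "'")
    k <- which(plain$reaction == rid)
    # loopless range is a subset of the plain range by construction
    plain$min[k] <- max(lo_best, plain$min[k])
    plain$max[k] <- min(hi_best, plain$max[k])
  }
  plain
}

#' Find blocked reactions
#'
#' A reaction is blocked under a medium iff both its minimal and maximal
#' achievable fluxes are zero (within [LK_FLUX_TOL]), i.e. no steady state
#' can route flux through it.
#'
#' @param model a `metabolic_model`.
#' @param med a [medium()] (may be `NULL` for the model's own bounds).
#' @return character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, med = NULL) {
  model <- apply_medium(model, med)
  probe <- fba(model)
  if (probe$status == "infeasible")
    stop("medium infeasible: no steady-state flux distribution exists")
  iv <- fva(model, fraction_of_optimum = 0)
  iv$reaction[abs(iv$min) < LK_FLUX_TOL & abs(iv$max) < LK_FLUX_TOL]
}
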