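# Minimization of metabolic adjustment (MOMA). A knockout strain is not
# assumed to re-optimize growth; its flux state is predicted as the feasible
# flux vector of the constrained network closest (in squared Euclidean
# distance) to the wild-type distribution. This is a convex QP — projection
# of the wild-type vector onto the knockout polytope — solved with the exact
# dual active-set method of quadprog.

#' Minimization of metabolic adjustment
#'
#' @param model a `metabolic_model` (the wild type).
#' @param wildtype a `flux_solution` from [fba()] on the same medium, or a
#'   named flux vector.
#' @param disabled_reactions reaction ids forced to zero flux (the knockout).
#' @param med optional [medium()] (should match the wild-type run).
#' @return a `flux_solution` whose `objective` is the growth rate of the
#'   adjusted flux state, with attribute `distance` (the squared flux
#'   deviation from wild type).
#' @export
moma <- function(model, wildtype, disabled_reactions = character(), med = NULL) {
  w <- if (inherits(wildtype, "flux_solution")) wildtype$fluxes else wildtype
  if (is.null(w)) stop("wild-type solution carries no flux vector")
  model <- apply_medium(model, med)
  if (length(disabled_reactions)) {
    i <- .rxn_index(model, disabled_reactions)
    model$reactions$lb[i] <- 0
    model$reactions$ub[i] <- 0
  }
  S <- stoichiometric_matrix(model)
  # quadprog rejects linearly dependent equality rows; keep an independent set
  qrS <- qr(t(S))
  S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  n <- n_reactions(model)
  m <- nrow(S)
  w <- w[model$reactions$id]
  # condition the QP: work in units of the largest bound and normalize the
  # balance rows, otherwise the active-set method mislabels the problem
  # infeasible on 1000-magnitude bounds
  sc <- max(abs(model$reactions$lb), abs(model$reactions$ub), 1)
  S <- S / sqrt(rowSums(S^2))
  # min ||v - w||^2, v = sc*u  <=>  min 1/2 u' (2I) u - (2w/sc)' u
  Amat <- cbind(t(S), diag(n), -diag(n))
  bvec <- c(numeric(m), model$reactions$lb / sc, -model$reactions$ub / sc)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(2, n), dvec = 2 * w / sc,
                       Amat = Amat, bvec = bvec, meq = m),
    error = function(e) NULL)
  if (is.null(sol)) {
    return(structure(list(status = "infeasible", objective = NA_real_,
                          objective_id = model$biomass, fluxes = NULL),
                     class = "flux_solution"))
  }
  v <- pmin(pmax(sol$solution * sc, model$reactions$lb), model$reactions$ub)
  names(v) <- model$reactions$id
  out <- structure(list(status = "optimal",
                        objective = v[[model$biomass]],
                        objective_id = model$biomass,
                        fluxes = v),
                   class = "flux_solution")
  attr(out, "distance") <- sum((v - w)^2)
  out
}
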