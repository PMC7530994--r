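# Expression-driven context-specific model extraction (GIMME) and
# differential-flux comparison of two contexts.
#
# GIMME keeps the network consistent with a required fraction of the
# metabolic objective while penalizing flux through reactions whose
# expression falls below a percentile threshold. The LP minimizes
# sum_i (threshold - score_i)+ * |v_i| over below-threshold reactions; a
# below-threshold reaction is removed iff it cannot carry flux in any
# penalty-minimal, objective-preserving state (confirmed by FVA under the
# inconsistency budget). Unscored reactions (no GPR or no data) are never
# removed.

#' Map gene expression onto reactions through GPRs
#'
#' @param model a `metabolic_model`.
#' @param profile named numeric vector of gene expression values (one
#'   condition), or a list with `condition` and `values`.
#' @return named numeric vector over reaction ids; `NA` = unscored.
#' @export
map_expression_to_reactions <- function(model, profile) {
  values <- if (is.list(profile)) profile$values else profile
  if (length(values) == 0L) stop("empty expression profile")
  scores <- vapply(model$reactions$gpr, gpr_score, numeric(1), values = values)
  names(scores) <- model$reactions$id
  scores
}

#' GIMME context-specific model extraction
#'
#' @param model a `metabolic_model` (parent).
#' @param scores reaction scores from [map_expression_to_reactions()].
#' @param med optional [medium()] defining the context's environment.
#' @param threshold_percentile expression percentile (of the scored-reaction
#'   distribution) below which a reaction is penalized; the conventional
#'   choice is 25.
#' @param required_objective_fraction fraction of the parent optimum the
#'   context model must retain (default 0.9).
#' @return an object of class `context_model`: list with `model` (pruned),
#'   `removed` (reaction ids), `removed_metabolites` (orphans dropped),
#'   `inconsistency` (GIMME objective), `threshold`, `parent_objective`.
#' @export
gimme <- function(model, scores, med = NULL, threshold_percentile = 25,
                  required_objective_fraction = 0.9) {
  model <- apply_medium(model, med)
  base <- fba(model)
  if (base$status != "optimal")
    stop("parent model infeasible under the context medium")
  mu_req <- required_objective_fraction * base$objective
  scored <- scores[!is.na(scores)]
  threshold <- as.numeric(stats::quantile(scored, threshold_percentile / 100,
                                          names = FALSE))
  pen_ids <- names(scored)[scored < threshold]
  if (length(pen_ids) == 0L) {
    return(structure(list(model = model, removed = character(),
                          removed_metabolites = character(),
                          inconsistency = 0, threshold = threshold,
                          parent_objective = base$objective),
                     class = "context_model"))
  }
  weights <- threshold - scored[pen_ids]
  n <- n_reactions(model)
  np <- length(pen_ids)
  S <- stoichiometric_matrix(model)
  pidx <- match(pen_ids, model$reactions$id)
  bi <- .rxn_index(model, model$biomass)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  lb[bi] <- max(lb[bi], mu_req)
  # variables: v (n), p (np), q (np) with v_i = p_i - q_i on penalized rxns
  big <- LK_BIG_BOUND
  A <- rbind(cbind(S, matrix(0, nrow(S), 2 * np)),
             cbind(.indicator_rows(n, pidx), -diag(np), diag(np)))
  obj <- c(numeric(n), weights, weights)
  lbf <- c(lb, numeric(2 * np))
  ubf <- c(ub, rep(big, 2 * np))
  sol <- solve_lp(obj, A, NULL, lbf, ubf, maximize = FALSE)
  if (sol$status != "optimal")
    stop("GIMME LP ", sol$status, ": objective requirement mu >= ",
         signif(mu_req, 6), " cannot be met")
  inconsistency <- sol$objective
  # removal confirmation: max |v_i| under the inconsistency budget; encode the
  # budget as an equality with a slack in [0, budget]
  budget <- inconsistency + 1e-6
  A2 <- rbind(cbind(A, matrix(0, nrow(A), 1)),
              c(numeric(n), weights, weights, 1))
  b2 <- c(numeric(nrow(A)), budget)
  lb2 <- c(lbf, 0); ub2 <- c(ubf, budget)
  removable <- vapply(seq_along(pen_ids), function(k) {
    objk <- numeric(n + 2 * np + 1)
    objk[n + k] <- 1; objk[n + np + k] <- 1      # p_k + q_k = |v_k|
    hi <- solve_lp(objk, A2, b2, lb2, ub2, maximize = TRUE)
    hi$status == "optimal" && hi$objective < LK_FLUX_TOL
  }, logical(1))
  removed <- pen_ids[removable]
  pruned <- .drop_reactions(model, removed)
  structure(list(model = pruned$model, removed = removed,
                 removed_metabolites = pruned$orphans,
                 inconsistency = inconsistency, threshold = threshold,
                 parent_objective = base$objective),
            class = "context_model")
}

.indicator_rows <- function(n, idx) {
  M <- matrix(0, length(idx), n)
  M[cbind(seq_along(idx), idx)] <- 1
  M
}

# drop reactions and any metabolites orphaned by the removal
.drop_reactions <- function(model, rids) {
  keep <- !(model$reactions$id %in% rids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  used <- unique(unlist(lapply(model$stoichiometry, names)))
  orphans <- setdiff(model$metabolites$id, used)
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  validate_model(model)
  list(model = model, orphans = orphans)
}

#' @export
print.context_model <- function(x, ...) {
  cat("Context-specific model (GIMME)\n")
  cat("  retained reactions:  ", n_reactions(x$model), "\n", sep = "")
  cat("  removed reactions:   ", length(x$removed), "\n", sep = "")
  cat("  retained metabolites:", n_metabolites(x$model), "\n")
  cat("  inconsistency score: ", signif(x$inconsistency, 6), "\n", sep = "")
  cat("  expression threshold:", signif(x$threshold, 6), "\n")
  invisible(x)
}

#' Jaccard index of two real intervals
#'
#' `J = |A intersect B| / |A union B|` with lengths measured on the real
#' line. Degenerate intervals (points) follow the convention: identical
#' points give 1, anything with no overlap gives 0, so `J = 0` remains
#' exactly the "no overlap" criterion.
#'
#' @param a,b numeric length-2 vectors `c(lo, hi)`, `lo <= hi`.
#' @return Jaccard index in \[0, 1\].
#' @export
interval_jaccard <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
  inter <- min(a[2], b[2]) - max(a[1], b[1])
  if (inter < 0) return(0)
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni == 0) return(1)       # both degenerate and coincident
  if (inter == 0) return(0)     # touching or a point against an interval
  inter / uni
}

#' Differential flux between two context models
#'
#' Runs loopless FVA on each context under its own medium, computes the
#' Jaccard index of the per-reaction flux intervals for reactions present in
#' both contexts, and flags `J = 0` (no overlap) as differential flux.
#' Reactions present in only one context are reported separately as
#' context-exclusive.
#'
#' @param ctx_a,ctx_b `context_model` objects (or plain `metabolic_model`s).
#' @param med_a,med_b the media of the two contexts.
#' @param fraction_of_optimum objective fraction for the FVA runs. The
#'   default 0.9 matches the objective fraction the contexts were extracted
#'   at; at 1.0 every interval collapses to a point and the degenerate
#'   Jaccard convention would flag any numerically distinct pair.
#' @return an object of class `differential_flux_report`: data.frame with
#'   `reaction`, `min_a`, `max_a`, `min_b`, `max_b`, `jaccard`, `flagged`,
#'   `subsystem`; attributes `exclusive_a`, `exclusive_b`.
#' @export
differential_flux <- function(ctx_a, ctx_b, med_a = NULL, med_b = NULL,
                              fraction_of_optimum = 0.9) {
  ma <- if (inherits(ctx_a, "context_model")) ctx_a$model else ctx_a
  mb <- if (inherits(ctx_b, "context_model")) ctx_b$model else ctx_b
  common <- intersect(ma$reactions$id, mb$reactions$id)
  iva <- loopless_fva(ma, med_a, fraction_of_optimum = fraction_of_optimum,
                      reactions = common)
  ivb <- loopless_fva(mb, med_b, fraction_of_optimum = fraction_of_optimum,
                      reactions = common)
  # snap endpoints below the LP noise floor to exactly zero, so a blocked
  # reaction is a true point at 0 in both contexts rather than a noise sliver
  snap <- function(x) ifelse(abs(x) < LK_FLUX_TOL, 0, x)
  jac <- vapply(seq_along(common), function(k) {
    interval_jaccard(snap(c(iva$min[k], iva$max[k])),
                     snap(c(ivb$min[k], ivb$max[k])))
  }, numeric(1))
  sub <- ma$reactions$subsystem[match(common, ma$reactions$id)]
  out <- data.frame(reaction = common,
                    min_a = iva$min, max_a = iva$max,
                    min_b = ivb$min, max_b = ivb$max,
                    jaccard = jac, flagged = jac == 0, subsystem = sub)
  rownames(out) <- NULL
  structure(out,
            exclusive_a = setdiff(ma$reactions$id, mb$reactions$id),
            exclusive_b = setdiff(mb$reactions$id, ma$reactions$id),
            class = c("differential_flux_report", "data.frame"))
}

#' Rank pathways by differential-flux burden
#'
#' Counts flagged reactions per subsystem, descending; ties break
#' lexicographically so the ranking is deterministic. Reactions without a
#' subsystem label are grouped under "unassigned".
#'
#' @param report a `differential_flux_report`.
#' @return data.frame with columns `subsystem`, `n_flagged`, `fraction` (of
#'   all flagged reactions).
#' @export
rank_pathways <- function(report) {
  fl <- report[report$flagged, , drop = FALSE]
  if (nrow(fl) == 0L)
    return(data.frame(subsystem = character(), n_flagged = integer(),
                      fraction = numeric()))
  sub <- ifelse(is.na(fl$subsystem) | !nzchar(fl$subsystem),
                "unassigned", fl$subsystem)
  tab <- table(sub)
  ord <- order(-as.integer(tab), names(tab))
  data.frame(subsystem = names(tab)[ord],
             n_flagged = as.integer(tab)[ord],
             fraction = as.integer(tab)[ord] / sum(tab))
}
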