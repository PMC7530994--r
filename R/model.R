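# The metabolic model container. A "metabolic_model" is a plain list holding
# compartments, a metabolite table, a reaction table, a stoichiometry list
# (reaction id -> named coefficient vector over metabolite ids, negative =
# substrate), the gene inventory and the id of the biomass pseudo-reaction.
# Flux bounds are in mmol/gdw/h; the conventional unconstrained magnitude is
# 1000. Exchange reactions are boundary reactions touching exactly one
# metabolite; their flux is negative for uptake and positive for secretion.

#' Default unconstrained flux bound (mmol/gdw/h)
#' @export
LK_BIG_BOUND <- 1000

#' Flux significance tolerance (mmol/gdw/h)
#'
#' Fluxes below this magnitude are treated as zero in blocked-reaction
#' detection, confidence scoring and viability calls; chosen above
#' double-precision LP noise.
#' @export
LK_FLUX_TOL <- 1e-6

#' Construct a metabolic model
#'
#' @param id model identifier.
#' @param compartments character vector of compartment ids (optionally named
#'   with display names).
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (string, may be `NA`), `charge` (integer, may be `NA`).
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`,
#'   `gpr` (rule string, `""` for none), `subsystem`; an optional
#'   `confidence` column (integer 1-4 or `NA`).
#' @param stoichiometry named list: for each reaction id, a named numeric
#'   vector of metabolite coefficients (negative = consumed).
#' @param biomass id of the biomass objective reaction.
#' @param genes optional character vector; defaults to the union of all GPR
#'   genes.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            stoichiometry, biomass, genes = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"confidence" %in% names(reactions)) reactions$confidence <- NA_integer_
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  model <- structure(list(
    id = id,
    compartments = compartments,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry[reactions$id],
    genes = genes,
    biomass = biomass
  ), class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate metabolic model invariants
#'
#' Checks id uniqueness, referential integrity of compartments and
#' stoichiometries, bound ordering, GPR gene coverage, the presence of the
#' biomass reaction, and that exchange reactions touch a single metabolite.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (nrow(rxns) == 0L) stop("model has no reactions")
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
                                   paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids: ",
                                   paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  bad_comp <- setdiff(mets$compartment, model$compartments)
  if (length(bad_comp)) stop("unknown compartments: ", paste(bad_comp, collapse = ", "))
  if (any(rxns$lb > rxns$ub))
    stop("lower bound exceeds upper bound for: ",
         paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxns$id) ||
      length(model$stoichiometry) != nrow(rxns))
    stop("stoichiometry list does not match reaction table")
  for (rid in rxns$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0L) stop("reaction '", rid, "' has empty stoichiometry")
    missing_met <- setdiff(names(st), mets$id)
    if (length(missing_met))
      stop("reaction '", rid, "' references unknown metabolites: ",
           paste(missing_met, collapse = ", "))
  }
  gpr_gene_set <- unique(unlist(lapply(rxns$gpr, gpr_genes)))
  orphan <- setdiff(gpr_gene_set, model$genes)
  if (length(orphan))
    stop("GPR genes absent from gene list: ", paste(orphan, collapse = ", "))
  if (!model$biomass %in% rxns$id)
    stop("biomass reaction '", model$biomass, "' not in model")
  invisible(model)
}

#' Exchange reaction ids
#'
#' Exchange (boundary) reactions touch exactly one metabolite; by convention
#' their stoichiometric entry is -1 so that negative flux means uptake.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  names(model$stoichiometry)[vapply(model$stoichiometry, length, integer(1)) == 1L]
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    S[names(st), rid] <- st
  }
  S
}

#' Number of reactions / metabolites / genes
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' @rdname n_reactions
#' @export
n_genes <- function(model) length(model$genes)

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  reactions:   ", n_reactions(x),
      " (", length(exchange_reactions(x)), " exchanges)\n", sep = "")
  cat("  metabolites: ", n_metabolites(x), "\n", sep = "")
  cat("  genes:       ", n_genes(x), "\n", sep = "")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  cat("  biomass:     ", x$biomass, "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  rev <- sum(object$reactions$lb < 0)
  out <- list(id = object$id,
              n_reactions = n_reactions(object),
              n_metabolites = n_metabolites(object),
              n_genes = n_genes(object),
              n_compartments = length(object$compartments),
              n_exchanges = length(exchange_reactions(object)),
              n_reversible = rev,
              n_irreversible = n_reactions(object) - rev,
              subsystems = sort(table(object$reactions$subsystem), decreasing = TRUE))
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("Model", x$id, ":", x$n_reactions, "reactions,", x$n_metabolites,
      "metabolites,", x$n_genes, "genes,", x$n_compartments, "compartments\n")
  cat("  reversible:", x$n_reversible, " irreversible:", x$n_irreversible, "\n")
  cat("  subsystems:\n")
  print(x$subsystems)
  invisible(x)
}

# index of a reaction id with a clear error
.rxn_index <- function(model, rid) {
  i <- match(rid, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id(s): ",
                     paste(rid[is.na(i)], collapse = ", "))
  i
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param rid reaction id.
#' @param lb,ub new bounds (either may be omitted to keep the current value).
#' @return the modified model.
#' @export
set_bounds <- function(model, rid, lb = NULL, ub = NULL) {
  i <- .rxn_index(model, rid)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  if (any(model$reactions$lb[i] > model$reactions$ub[i]))
    stop("lower bound exceeds upper bound for '", rid, "'")
  model
}

#' Define a growth medium
#'
#' A medium is a named set of exchange uptake allowances: applying it closes
#' every exchange uptake (lower bound 0) and then opens uptake for the listed
#' exchanges at `lower bound = -uptake`. Secretion is left unconstrained.
#'
#' @param name medium name.
#' @param uptake named numeric vector, exchange reaction id -> maximal uptake
#'   magnitude (mmol/gdw/h, >= 0).
#' @return an object of class `medium`.
#' @export
medium <- function(name, uptake) {
  if (any(uptake < 0)) stop("uptake magnitudes must be >= 0")
  structure(list(name = name, uptake = uptake), class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("Medium '", x$name, "': ", length(x$uptake), " uptakes\n", sep = "")
  for (i in seq_along(x$uptake))
    cat(sprintf("  %-16s %g\n", names(x$uptake)[i], x$uptake[i]))
  invisible(x)
}

#' Apply a medium to a model
#'
#' @param model a `metabolic_model`.
#' @param med a [medium()], or `NULL` to leave bounds untouched.
#' @return model with exchange bounds set.
#' @export
apply_medium <- function(model, med) {
  if (is.null(med)) return(model)
  ex <- exchange_reactions(model)
  unknown <- setdiff(names(med$uptake), ex)
  if (length(unknown))
    stop("medium '", med$name, "' names non-exchange reactions: ",
         paste(unknown, collapse = ", "))
  i <- match(ex, model$reactions$id)
  model$reactions$lb[i] <- 0
  j <- match(names(med$uptake), model$reactions$id)
  model$reactions$lb[j] <- -med$uptake
  model
}
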