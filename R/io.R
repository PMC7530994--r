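# Model serialization. Two dialects are supported:
#
#  * a human-diffable JSON dialect: one object with arrays "metabolites",
#    "reactions" and "genes", each entry mirroring the container fields;
#    reaction stoichiometry is a {metabolite: coefficient} map and the GPR is
#    a parenthesized Boolean string with "and"/"or";
#  * SBML Level 3 with the fbc flux-bounds extension (the subset emitted by
#    mainstream constraint-based toolchains: species with chemicalFormula
#    and charge, bound parameters, geneProductAssociation trees, one
#    maximization objective).
#
# Metabolite ids carrying a legacy "_<compartment>" suffix are accepted on
# read, but the compartment field is authoritative.

#' Read a metabolic model
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension by default.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") .read_model_json(path) else .read_model_sbml(path)
}

#' Write a metabolic model
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"json"` or `"sbml"`; guessed from the extension by default.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (format == "json") .write_model_json(model, path) else .write_model_sbml(model, path)
  invisible(path)
}

.read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("JSON parse error in '", path, "': ",
                                           conditionMessage(e)))
  for (key in c("metabolites", "reactions"))
    if (is.null(doc[[key]])) stop("model file lacks a '", key, "' array")
  if (length(doc$reactions) == 0L) stop("model has no reactions")
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in '", path, "'")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% .suffix_compartment(m$id),
               formula = m$formula %||% NA_character_,
               charge = as.integer(m$charge %||% NA_integer_))
  }))
  stoich <- list()
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in '", path, "'")
    if (is.null(r$metabolites) || length(r$metabolites) == 0L)
      stop("reaction '", r$id, "' has no stoichiometry")
    st <- unlist(r$metabolites)
    stoich[[r$id]] <<- st
    lb <- r$lower_bound; ub <- r$upper_bound
    if (is.null(lb) || is.null(ub)) {
      message("reaction '", r$id, "': missing bounds filled with (-",
              LK_BIG_BOUND, ", ", LK_BIG_BOUND, ")")
      lb <- lb %||% -LK_BIG_BOUND
      ub <- ub %||% LK_BIG_BOUND
    }
    data.frame(id = r$id, name = r$name %||% r$id, lb = lb, ub = ub,
               gpr = r$gene_reaction_rule %||% "",
               subsystem = r$subsystem %||% "",
               confidence = as.integer(r$confidence %||% NA_integer_))
  }))
  genes <- if (!is.null(doc$genes))
    vapply(doc$genes, function(g) g$id %||% g, character(1)) else NULL
  comps <- if (!is.null(doc$compartments)) {
    if (is.list(doc$compartments)) names(unlist(doc$compartments)) else unlist(doc$compartments)
  } else unique(mets$compartment)
  biomass <- doc$biomass %||% doc$objective %||%
    stop("model file names no biomass/objective reaction")
  metabolic_model(id = doc$id %||% basename(path), compartments = comps,
                  metabolites = mets, reactions = rxns, stoichiometry = stoich,
                  biomass = biomass, genes = genes)
}

.write_model_json <- function(model, path) {
  drop_null <- function(l) l[!vapply(l, is.null, logical(1))]
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    drop_null(list(id = m$id, name = m$name, compartment = m$compartment,
         formula = if (is.na(m$formula)) NULL else m$formula,
         charge = if (is.na(m$charge)) NULL else m$charge))
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    drop_null(list(id = r$id, name = r$name,
         metabolites = as.list(model$stoichiometry[[r$id]]),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = r$gpr, subsystem = r$subsystem,
         confidence = if (is.na(r$confidence)) NULL else r$confidence))
  })
  doc <- list(id = model$id,
              compartments = as.list(stats::setNames(model$compartments,
                                                     model$compartments)),
              metabolites = mets, reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g)),
              biomass = model$biomass)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.suffix_compartment <- function(id) {
  if (grepl("_[a-z]$", id)) sub(".*_", "", id) else "c"
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# ---------------------------------------------------------------- SBML ----

.SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  san <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            .SBML_NS, .FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', san(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', san(model$compartments)),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$formula) && nzchar(m$formula))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', m$formula))
    if (!is.na(m$charge))
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', as.integer(m$charge)))
    lines <- c(lines, sprintf(
      '      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      san(m$id), esc(m$name), san(m$compartment), extra))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  bnd_id <- function(i, side) sprintf("%s_%s", side, i)
  for (i in seq_len(nrow(model$reactions))) {
    lines <- c(lines,
      sprintf('      <parameter id="%s" value="%.10g" constant="true"/>',
              bnd_id(i, "lb"), model$reactions$lb[i]),
      sprintf('      <parameter id="%s" value="%.10g" constant="true"/>',
              bnd_id(i, "ub"), model$reactions$ub[i]))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  gpr_xml <- function(expr, indent) {
    pad <- strrep(" ", indent)
    if (is.character(expr))
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>', pad, san(expr)))
    tag <- if (expr$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(expr$args, gpr_xml, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      san(r$id), esc(r$name), tolower(r$lb < 0), bnd_id(i, "lb"), bnd_id(i, "ub")))
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>',
        sprintf('          <speciesReference species="%s" stoichiometry="%.10g" constant="true"/>',
                san(names(subs)), -as.numeric(subs)),
        '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="%.10g" constant="true"/>',
                san(names(prods)), as.numeric(prods)),
        '        </listOfProducts>')
    }
    expr <- gpr_parse(r$gpr)
    if (!is.null(expr)) {
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpr_xml(expr, 10), '        </fbc:geneProductAssociation>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            san(model$biomass)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '    <fbc:listOfGeneProducts>',
    sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
            san(model$genes), esc(model$genes)),
    '    </fbc:listOfGeneProducts>',
    '  </model>', '</sbml>')
  writeLines(lines, path)
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path, "': ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)   # work with local names; fbc attrs keep their prefix
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML file has no <model> element")
  attr_or <- function(node, name, default = NA_character_) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  comps <- xml2::xml_attr(xml2::xml_find_all(mdl, ".//listOfCompartments/compartment"), "id")
  if (length(comps) == 0L) comps <- "c"
  sp <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp, "charge"))))
  pars <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  if (length(rx) == 0L) stop("model has no reactions")
  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
    kids <- lapply(xml2::xml_children(node), parse_assoc)
    list(op = if (nm == "and") "and" else "or", args = kids)
  }
  stoich <- list()
  rows <- lapply(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    st <- numeric()
    for (sr in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      met <- xml2::xml_attr(sr, "species")
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      met <- xml2::xml_attr(sr, "species")
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    if (length(st) == 0L) stop("reaction '", rid, "' has no stoichiometry")
    stoich[[rid]] <<- st
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else NA_real_
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else NA_real_
    if (is.na(lb) || is.na(ub)) {
      message("reaction '", rid, "': missing bounds filled with (-",
              LK_BIG_BOUND, ", ", LK_BIG_BOUND, ")")
      if (is.na(lb)) lb <- if (identical(xml2::xml_attr(r, "reversible"), "false"))
        0 else -LK_BIG_BOUND
      if (is.na(ub)) ub <- LK_BIG_BOUND
    }
    ga <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(ga, "xml_missing")) "" else {
      kids <- xml2::xml_children(ga)
      if (length(kids)) gpr_deparse(parse_assoc(kids[[1]])) else ""
    }
    data.frame(id = rid, name = attr_or(r, "name", rid), lb = lb, ub = ub,
               gpr = gpr, subsystem = "", confidence = NA_integer_)
  })
  rxns <- do.call(rbind, rows)
  genes <- xml2::xml_attr(
    xml2::xml_find_all(mdl, ".//*[local-name()='geneProduct']"), "id")
  flux_obj <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  biomass <- if (!inherits(flux_obj, "xml_missing"))
    xml2::xml_attr(flux_obj, "reaction")
  else stop("SBML file declares no flux objective; cannot identify biomass")
  metabolic_model(id = attr_or(mdl, "id", basename(path)),
                  compartments = comps, metabolites = mets, reactions = rxns,
                  stoichiometry = stoich, biomass = biomass,
                  genes = if (length(genes)) genes else NULL)
}
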