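#' Write a model as BiGG-style JSON
#'
#' The dialect mirrors the BiGG JSON schema: `metabolites[]` (id, name,
#' compartment, formula, charge), `reactions[]` (id, metabolites map,
#' lower_bound, upper_bound, gene_reaction_rule, subsystem), `genes[]`, and
#' the objective reaction id. Pseudo status is carried by the id prefix
#' (`EX_`/`SK_`/`DM_`/`BIOMASS`), as in BiGG models.
#'
#' @param model a `gem_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment,
         formula = if (is.na(m$formula)) NULL else m$formula,
         charge = m$charge)
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$id,
         metabolites = as.list(r$stoich),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = gpr_deparse(r$gpr),
         subsystem = r$subsystem)
  })
  genes <- lapply(model_genes(model), function(g) list(id = g))
  doc <- list(id = model$id, metabolites = mets, reactions = unname(rxns),
              genes = genes, objective = model$objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model from BiGG-style JSON
#'
#' @param path file written by [write_model_json()] or a compatible BiGG
#'   export.
#' @return a `gem_model`.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  model <- gem_model(id = doc$id %||% "model")
  for (m in doc$metabolites) {
    model <- add_metabolite(model, id = m$id, name = m$name %||% m$id,
                            formula = m$formula %||% NA_character_,
                            charge = as.integer(m$charge %||% 0L),
                            compartment = m$compartment %||% met_compartment(m$id))
  }
  for (r in doc$reactions) {
    st <- vapply(r$metabolites, as.numeric, numeric(1))
    model <- add_reaction(model, id = r$id, stoich = st,
                          lb = as.numeric(r$lower_bound %||% -1000),
                          ub = as.numeric(r$upper_bound %||% 1000),
                          gpr = r$gene_reaction_rule %||% "",
                          subsystem = r$subsystem %||% "")
  }
  if (!is.null(doc$objective) && !is.na(doc$objective)) {
    model <- set_objective(model, doc$objective)
  }
  validate_model(model)
  model
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_safe <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

#' Write a model as SBML Level 3 with the fbc package
#'
#' Bounds become shared `Parameter`s referenced through `fbc:lowerFluxBound` /
#' `fbc:upperFluxBound`, GPR rules become `fbc:geneProductAssociation` trees
#' and the objective an `fbc:listOfObjectives` entry. Ids are prefixed
#' (`M_`, `R_`, `G_`) per the SBML identifier conventions.
#'
#' @param model a `gem_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_safe(model$id),
                             "fbc:strict" = "true")
  cmps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(cmps, "compartment", id = cid, constant = "true")
  }
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(sps, "species",
      id = paste0("M_", sbml_safe(m$id)), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false",
      "fbc:charge" = as.character(m$charge))
    if (!is.na(m$formula) && nzchar(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
  }
  # shared flux-bound parameters
  bounds <- unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub))))
  bid <- function(v) paste0("B_", gsub("[-.]", "_", format(v, scientific = FALSE)))
  prs <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(prs, "parameter", id = bid(v),
                        value = format(v, digits = 15, scientific = FALSE),
                        constant = "true", sboTerm = "SBO:0000626")
  }
  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model_genes(model)) {
    xml2::xml_add_child(gps, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sbml_safe(g)), "fbc:label" = g)
  }
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  add_gpa <- function(parent, node) {
    if (!is.null(node$gene)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", sbml_safe(node$gene)))
    } else {
      grp <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
      for (a in node$args) add_gpa(grp, a)
    }
  }
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(rxs, "reaction",
      id = paste0("R_", sbml_safe(r$id)),
      reversible = if (r$lb < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid(r$lb), "fbc:upperFluxBound" = bid(r$ub))
    if (nzchar(r$subsystem)) xml2::xml_set_attr(rx, "name", r$subsystem)
    subs <- r$stoich[r$stoich < 0]; prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(subs)) {
        xml2::xml_add_child(lr, "speciesReference",
          species = paste0("M_", sbml_safe(names(subs)[k])),
          stoichiometry = format(-subs[[k]], digits = 15), constant = "true")
      }
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prods)) {
        xml2::xml_add_child(lp, "speciesReference",
          species = paste0("M_", sbml_safe(names(prods)[k])),
          stoichiometry = format(prods[[k]], digits = 15), constant = "true")
      }
    }
    if (!is.null(r$gpr)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_gpa(gpa, unclass(r$gpr))
    }
  }
  if (!is.na(model$objective)) {
    los <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(los, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sbml_safe(model$objective)),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML Level 3 (fbc)
#'
#' Understands the subset written by [write_model_sbml()]: species with
#' fbc charge/formula, reactions with flux-bound parameters and
#' geneProductAssociation trees, and an active maximization objective.
#'
#' @param path SBML file.
#' @return a `gem_model`.
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  model <- gem_model(id = xml2::xml_attr(mdl, "id"))
  unprefix <- function(x, p) sub(paste0("^", p), "", x)
  # gene labels keyed by fbc id
  gp <- xml2::xml_find_all(mdl, ".//fbc:geneProduct", ns)
  glab <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))
  for (sp in xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)) {
    id <- unprefix(xml2::xml_attr(sp, "id"), "M_")
    chg <- xml2::xml_attr(sp, "charge")
    nm <- xml2::xml_attr(sp, "name")
    model <- add_metabolite(model, id = id,
      name = if (is.na(nm)) id else nm,
      formula = xml2::xml_attr(sp, "chemicalFormula"),
      charge = as.integer(if (is.na(chg)) 0L else chg),
      compartment = xml2::xml_attr(sp, "compartment"))
  }
  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lab <- unname(glab[gid])
      return(list(gene = if (is.null(lab) || is.na(lab)) unprefix(gid, "G_") else lab))
    }
    kids <- xml2::xml_children(node)
    if (nm %in% c("and", "or")) {
      return(list(op = nm, args = lapply(kids, parse_gpa)))
    }
    # geneProductAssociation wrapper: single child
    parse_gpa(kids[[1]])
  }
  for (rx in xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)) {
    id <- unprefix(xml2::xml_attr(rx, "id"), "R_")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)) {
      met <- unprefix(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- (st[met] %|0|% 0) - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)) {
      met <- unprefix(xml2::xml_attr(sr, "species"), "M_")
      st[met] <- (st[met] %|0|% 0) + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(rx, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) NULL else
      structure(parse_gpa(gpa), class = "gemflux_gpr")
    subsystem <- xml2::xml_attr(rx, "name")
    model <- add_reaction(model, id = id, stoich = st,
      lb = unname(pval[xml2::xml_attr(rx, "lowerFluxBound")]),
      ub = unname(pval[xml2::xml_attr(rx, "upperFluxBound")]),
      gpr = gpr,
      subsystem = if (is.na(subsystem)) "" else subsystem)
  }
  fo <- xml2::xml_find_first(mdl, ".//fbc:fluxObjective", ns)
  if (!inherits(fo, "xml_missing")) {
    model <- set_objective(model, unprefix(xml2::xml_attr(fo, "reaction"), "R_"))
  }
  validate_model(model)
  model
}

`%|0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
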