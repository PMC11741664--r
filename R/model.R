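#' Compartmentalized constraint-based metabolic models
#'
#' A `gem_model` is the package's central container: a stoichiometric network
#' over three compartments (`c` cytoplasm, `p` periplasm, `e` extracellular)
#' with BiGG-style lowercase identifiers carrying a `_c`/`_p`/`_e` suffix,
#' flux bounds in mmol/gDW/h, boolean GPR rules and a biomass objective.
#' Reversibility is implied by the bounds alone: a negative lower bound means
#' the reaction may run in reverse. Exchange (`EX_`), sink (`SK_`), demand
#' (`DM_`) and biomass reactions are pseudo reactions: modeling devices that
#' are skipped by mass/charge balance checks and deletion screens.
#'
#' @param id model identifier.
#' @return an empty `gem_model`.
#' @seealso [add_metabolite()], [add_reaction()], [build_stoichiometric_matrix()]
#' @export
gem_model <- function(id = "model") {
  structure(list(
    id = id,
    metabolites = data.frame(id = character(0), name = character(0),
                             formula = character(0), charge = integer(0),
                             compartment = character(0), stringsAsFactors = FALSE),
    reactions = list(),
    objective = NA_character_,
    template_genes = character(0),
    couplings = list()
  ), class = "gem_model")
}

PSEUDO_PREFIXES <- c("EX_", "SK_", "DM_", "BIOMASS")

met_compartment <- function(id) {
  suf <- sub("^.*_([cpe])$", "\\1", id)
  if (identical(suf, id)) NA_character_ else suf
}

#' Add a metabolite to a model
#'
#' @param model a `gem_model`.
#' @param id metabolite id with compartment suffix, e.g. `"ac_c"`.
#' @param name human-readable name.
#' @param formula chemical formula string (may be `NA` for pool metabolites).
#' @param charge integer charge.
#' @param compartment one of `"c"`, `"p"`, `"e"`; defaults to the id suffix.
#' @return the updated model.
#' @export
add_metabolite <- function(model, id, name = id, formula = NA_character_,
                           charge = 0L, compartment = met_compartment(id)) {
  stopifnot(inherits(model, "gem_model"))
  if (id %in% model$metabolites$id) stop("duplicate metabolite id: ", id)
  if (is.na(compartment) || !compartment %in% c("c", "p", "e")) {
    stop("metabolite '", id, "' has no valid compartment suffix")
  }
  if (!identical(met_compartment(id), compartment)) {
    stop("metabolite '", id, "' suffix disagrees with compartment '", compartment, "'")
  }
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = id, name = name, formula = formula, charge = as.integer(charge),
    compartment = compartment, stringsAsFactors = FALSE))
  model
}

is_pseudo_id <- function(id) {
  any(startsWith(toupper(id), PSEUDO_PREFIXES))
}

#' Add a reaction to a model
#'
#' @param model a `gem_model`.
#' @param id reaction id. Ids starting with `EX_`, `SK_`, `DM_` or `BIOMASS`
#'   must be flagged `pseudo = TRUE` (and vice versa); the mismatch is a
#'   loading error, so file conventions and flags cannot drift apart.
#' @param stoich named numeric vector of signed coefficients (negative =
#'   substrate); all names must resolve to metabolites already in the model.
#' @param lb,ub flux bounds in mmol/gDW/h; `lb <= ub` required.
#' @param gpr GPR rule string or tree (see [gpr_parse()]); empty for orphans.
#' @param subsystem subsystem label used by activity and regulation analyses.
#' @param pseudo logical, exchange/sink/demand/biomass flag.
#' @return the updated model.
#' @export
add_reaction <- function(model, id, stoich, lb = -1000, ub = 1000,
                         gpr = NULL, subsystem = "", pseudo = is_pseudo_id(id)) {
  stopifnot(inherits(model, "gem_model"))
  if (id %in% names(model$reactions)) stop("duplicate reaction id: ", id)
  if (length(stoich) == 0) stop("reaction '", id, "' has empty stoichiometry")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich)))) {
    stop("reaction '", id, "' stoichiometry must be a named vector")
  }
  missing <- setdiff(names(stoich), model$metabolites$id)
  if (length(missing) > 0) {
    stop("reaction '", id, "' references unknown metabolite(s): ",
         paste(missing, collapse = ", "))
  }
  if (lb > ub) stop("reaction '", id, "' has lb > ub")
  if (pseudo != is_pseudo_id(id)) {
    stop("reaction '", id, "': pseudo flag (", pseudo,
         ") disagrees with its id prefix; refusing to load")
  }
  if (is.character(gpr)) gpr <- gpr_parse(gpr)
  model$reactions[[id]] <- list(
    id = id, stoich = stoich, lb = lb, ub = ub, gpr = gpr,
    subsystem = subsystem, pseudo = pseudo)
  model
}

#' Reaction ids of a model
#' @param model a `gem_model`.
#' @return character vector in model order.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Metabolite ids of a model
#' @param model a `gem_model`.
#' @return character vector in model order.
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' Gene ids of a model
#' @param model a `gem_model`.
#' @return sorted character vector of all genes appearing in GPR rules.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr)))))
}

#' Is a reaction an orphan?
#'
#' An orphan reaction carries no gene association and is not a pseudo
#' reaction. Gap-filled reactions without genomic support end up here.
#'
#' @param model a `gem_model`.
#' @return named logical vector over reactions.
#' @export
orphan_reactions <- function(model) {
  vapply(model$reactions, function(r) is.null(r$gpr) && !r$pseudo, logical(1))
}

#' Set the model objective
#' @param model a `gem_model`.
#' @param reaction_id id of the (biomass) reaction to optimize.
#' @return the updated model.
#' @export
set_objective <- function(model, reaction_id) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("objective reaction '", reaction_id, "' not in model")
  }
  model$objective <- reaction_id
  model
}

#' Set flux bounds on a reaction
#' @param model a `gem_model`.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds; omit either to keep it.
#' @return the updated model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("unknown reaction: ", reaction_id)
  }
  if (!is.null(lb)) model$reactions[[reaction_id]]$lb <- unname(lb)
  if (!is.null(ub)) model$reactions[[reaction_id]]$ub <- unname(ub)
  r <- model$reactions[[reaction_id]]
  if (r$lb > r$ub) stop("bounds cross for reaction ", reaction_id)
  model
}

#' Exchange reaction ids
#' @param model a `gem_model`.
#' @return character vector of reactions with the `EX_` prefix.
#' @export
exchange_ids <- function(model) {
  ids <- reaction_ids(model)
  ids[startsWith(ids, "EX_")]
}

#' Build the stoichiometric matrix
#'
#' @param model a `gem_model`.
#' @return sparse [Matrix::sparseMatrix] with one row per metabolite and one
#'   column per reaction; entry `S[i, j]` is the signed coefficient of
#'   metabolite `i` in reaction `j`.
#' @export
build_stoichiometric_matrix <- function(model) {
  mets <- metabolite_ids(model)
  rxns <- reaction_ids(model)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxns)) {
    st <- model$reactions[[j]]$stoich
    idx <- match(names(st), mets)
    if (anyNA(idx)) {
      stop("reaction '", rxns[j], "' references unresolved metabolite(s): ",
           paste(names(st)[is.na(idx)], collapse = ", "))
    }
    ii <- c(ii, idx); jj <- c(jj, rep.int(j, length(st))); xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rxns)),
                       dimnames = list(mets, rxns))
}

#' Validate model invariants
#'
#' Checks id uniqueness, compartment suffix agreement, stoichiometry
#' resolution, bound ordering and pseudo-prefix agreement; errors on the
#' first violation.
#'
#' @param model a `gem_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "gem_model"))
  if (anyDuplicated(model$metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(names(model$reactions))) stop("duplicate reaction ids")
  ok <- mapply(function(id, cmp) identical(met_compartment(id), cmp),
               model$metabolites$id, model$metabolites$compartment)
  if (!all(ok)) stop("compartment suffix mismatch: ",
                     paste(model$metabolites$id[!ok], collapse = ", "))
  for (r in model$reactions) {
    if (r$lb > r$ub) stop("lb > ub in reaction ", r$id)
    if (r$pseudo != is_pseudo_id(r$id)) stop("pseudo flag mismatch in ", r$id)
    missing <- setdiff(names(r$stoich), model$metabolites$id)
    if (length(missing)) stop("unresolved metabolites in ", r$id)
  }
  invisible(model)
}

#' @export
print.gem_model <- function(x, ...) {
  orph <- sum(orphan_reactions(x))
  cat("gem_model '", x$id, "': ", nrow(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", orph, " orphan), ",
      length(model_genes(x)), " genes\n", sep = "")
  cat("objective:", x$objective, "\n")
  invisible(x)
}

#' Remove a reaction (internal helper)
#' @noRd
drop_reaction <- function(model, reaction_id) {
  model$reactions[[reaction_id]] <- NULL
  model
}
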