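#' Single-gene deletion screen
#'
#' For each gene and condition, every reaction whose GPR rule evaluates false
#' with that gene removed (a complex loses a subunit; an isozyme set survives
#' as long as one member remains) is disabled, FBA is re-solved, and the
#' knockout/wild-type growth ratio classifies the deletion:
#' `non_essential` (ratio ~ 1), `growth_reducing` (tolerance < ratio < 1) or
#' `lethal` (knockout growth below the tolerance). Orphan reactions carry no
#' genes and are never disabled by a gene deletion.
#'
#' A deletion whose disabled reactions all carry zero flux in the wild-type
#' optimum cannot change the optimum (the wild-type solution stays feasible
#' and deletions never increase growth), so those LPs are skipped.
#'
#' @param model a `gem_model`.
#' @param conditions named list of [growth_condition()]s; wild-type growth
#'   must be positive in each.
#' @param genes subset of genes to screen (default: all model genes).
#' @return list with `records` (entity, condition, ko_mu, ratio, class) and
#'   `summary` from [summarize_essentiality()].
#' @export
single_gene_deletion <- function(model, conditions, genes = model_genes(model)) {
  screen_deletions(model, conditions, entities = genes, by = "gene")
}

#' Single-reaction deletion screen
#'
#' Pins the bounds of each deleted reaction to zero and re-solves per
#' condition. Pseudo reactions (exchanges, sinks, demands, biomass) are
#' modeling devices and are excluded by default; orphan reactions are
#' included and labeled in the records.
#'
#' @param model a `gem_model`.
#' @param conditions named list of [growth_condition()]s.
#' @param exclude_pseudo drop pseudo reactions from the screen (default TRUE).
#' @return list with `records` (plus an `orphan` flag per record) and
#'   `summary`.
#' @export
single_reaction_deletion <- function(model, conditions, exclude_pseudo = TRUE) {
  rxns <- reaction_ids(model)
  if (exclude_pseudo) {
    rxns <- rxns[!vapply(model$reactions, function(r) r$pseudo, logical(1))]
  }
  out <- screen_deletions(model, conditions, entities = rxns, by = "reaction")
  orph <- orphan_reactions(model)
  out$records$orphan <- unname(orph[out$records$entity])
  out
}

screen_deletions <- function(model, conditions, entities, by) {
  stopifnot(by %in% c("gene", "reaction"), length(conditions) >= 1)
  if (is.null(names(conditions))) {
    names(conditions) <- vapply(conditions, function(c) c$id, character(1))
  }
  gene_rxn_map <- NULL
  if (by == "gene") {
    gene_rxn_map <- lapply(stats::setNames(nm = entities), function(g) {
      hit <- vapply(model$reactions, function(r) {
        !is.null(r$gpr) && g %in% gpr_genes(r$gpr) && !gpr_eval(r$gpr, g)
      }, logical(1))
      names(hit)[hit]
    })
  }
  rows <- list()
  for (cid in names(conditions)) {
    constrained <- apply_condition(model, conditions[[cid]])
    wt <- solve_fba(constrained)
    if (wt$status != "optimal" || wt$objective_value <= GROWTH_TOL) {
      stop("wild type does not grow under condition '", cid, "'")
    }
    wt_mu <- wt$objective_value
    wt_flux <- wt$fluxes
    for (ent in entities) {
      disabled <- if (by == "gene") gene_rxn_map[[ent]] else ent
      if (length(disabled) == 0 ||
          all(abs(wt_flux[disabled]) <= GROWTH_TOL)) {
        ko_mu <- wt_mu   # wild-type optimum unaffected by the deletion
      } else {
        kom <- constrained
        for (rid in disabled) kom <- set_bounds(kom, rid, lb = 0, ub = 0)
        sol <- solve_fba(kom)
        ko_mu <- if (sol$status == "optimal") sol$objective_value else 0
      }
      ratio <- ko_mu / wt_mu
      if (ratio > 1 && ratio <= 1 + GROWTH_TOL) ratio <- 1
      cls <- if (ratio >= 1 - GROWTH_TOL) "non_essential"
             else if (ko_mu <= GROWTH_TOL) "lethal"
             else "growth_reducing"
      rows[[length(rows) + 1]] <- data.frame(
        entity = ent, condition = cid, ko_mu = ko_mu, ratio = ratio,
        class = cls, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records,
       summary = summarize_essentiality(records))
}

#' Aggregate per-condition deletion records into global classes
#'
#' Two aggregation rules are in use in genome-scale screens and both are
#' available: `"all"` labels an entity lethal only when it is lethal in
#' every condition (the gene-essentiality convention), `"any"` when it is
#' lethal in at least one condition (the convention of polymer-production
#' reaction screens). Growth-reducing means reduced in at least one
#' condition; lethal takes precedence; everything else is non-essential.
#' The three classes partition the entities.
#'
#' @param records records data.frame from a deletion screen.
#' @param lethal_rule `"all"` or `"any"`.
#' @return data.frame `entity`, `global_class`, `n_lethal`, `n_reducing`,
#'   `n_conditions`.
#' @export
summarize_essentiality <- function(records, lethal_rule = "all") {
  stopifnot(lethal_rule %in% c("all", "any"))
  sp <- split(records, records$entity)
  rows <- lapply(sp, function(d) {
    n_let <- sum(d$class == "lethal")
    n_red <- sum(d$class == "growth_reducing")
    lethal <- if (lethal_rule == "all") n_let == nrow(d) else n_let > 0
    cls <- if (lethal) "lethal"
           else if (n_red > 0 || n_let > 0) "growth_reducing"
           else "non_essential"
    data.frame(entity = d$entity[1], global_class = cls,
               n_lethal = n_let, n_reducing = n_red, n_conditions = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Upset-style comparison of lethal sets across condition groups
#'
#' Takes one lethal-entity set per group (e.g. per polymer x oxygen regime)
#' and partitions the union into exact membership groups: each entity belongs
#' to exactly one combination of groups. Optionally attaches the subsystem
#' histogram of each membership group.
#'
#' @param lethal_sets named list of character vectors (lethal entities per
#'   group); at least two groups.
#' @param model optional `gem_model` supplying subsystems for the
#'   composition histograms.
#' @return list with `groups` (data.frame: `pattern` such as `"A&B"`,
#'   `count`, `members` as a list-column) and `subsystems` (named list of
#'   tables, `NULL` without a model).
#' @export
lethal_set_comparison <- function(lethal_sets, model = NULL) {
  stopifnot(length(lethal_sets) >= 2, !is.null(names(lethal_sets)))
  all_ent <- sort(unique(unlist(lethal_sets)))
  membership <- vapply(lethal_sets, function(s) all_ent %in% s,
                       logical(length(all_ent)))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row) {
    paste(names(lethal_sets)[row], collapse = "&")
  })
  sp <- split(all_ent, pattern)
  groups <- data.frame(pattern = names(sp),
                       count = vapply(sp, length, integer(1)),
                       stringsAsFactors = FALSE)
  groups$members <- unname(sp)
  groups <- groups[order(-groups$count), ]
  rownames(groups) <- NULL
  subsystems <- NULL
  if (!is.null(model)) {
    subs <- vapply(model$reactions, function(r) r$subsystem, character(1))
    subsystems <- lapply(groups$members, function(ms) table(subs[ms]))
    names(subsystems) <- groups$pattern
  }
  list(groups = groups, subsystems = subsystems)
}

#' Write deletion-screen output as TSV
#'
#' @param screen result of [single_gene_deletion()] or
#'   [single_reaction_deletion()].
#' @param dir output directory.
#' @param prefix file-name prefix (`gene` / `reaction`).
#' @return file paths, invisibly.
#' @export
write_essentiality <- function(screen, dir, prefix = "gene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_deletion_records.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_deletion_summary.tsv"))
  utils::write.table(screen$records, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(screen$summary, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
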