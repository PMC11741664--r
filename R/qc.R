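#' Mass and charge balance of every reaction
#'
#' For each non-pseudo reaction the per-element imbalance is the stoichiometry-
#' weighted sum of the element counts of its metabolites, and the charge
#' imbalance the weighted sum of charges. Element counts are integers, so the
#' comparison is exact: a reaction is balanced iff every imbalance is zero.
#' Pseudo reactions (exchanges, sinks, demands, biomass) move matter across
#' the system boundary by design and are skipped. A reaction touching a
#' metabolite without a formula cannot be checked and is flagged
#' `uncheckable` rather than crashing the run.
#'
#' @param model a `gem_model`.
#' @return data.frame with one row per non-pseudo reaction: `reaction_id`,
#'   `balanced`, `uncheckable`, `element_imbalance` (formula-style string of
#'   the nonzero element imbalances), `charge_imbalance`.
#' @export
check_mass_charge_balance <- function(model) {
  mets <- model$metabolites
  rows <- lapply(model$reactions, function(r) {
    if (r$pseudo) return(NULL)
    idx <- match(names(r$stoich), mets$id)
    formulas <- mets$formula[idx]
    if (anyNA(formulas) || any(!nzchar(formulas))) {
      return(data.frame(reaction_id = r$id, balanced = NA, uncheckable = TRUE,
                        element_imbalance = NA_character_,
                        charge_imbalance = NA_integer_, stringsAsFactors = FALSE))
    }
    total <- numeric(0)
    for (k in seq_along(idx)) {
      counts <- parse_formula(formulas[k])
      for (el in names(counts)) {
        total[el] <- (if (el %in% names(total)) total[[el]] else 0) +
          r$stoich[[k]] * counts[[el]]
      }
    }
    total <- total[abs(total) > 1e-9]
    chg <- sum(r$stoich * mets$charge[idx])
    data.frame(reaction_id = r$id,
               balanced = length(total) == 0 && abs(chg) < 1e-9,
               uncheckable = FALSE,
               element_imbalance = if (length(total) == 0) "" else
                 paste0(names(total), ":", total, collapse = ","),
               charge_imbalance = as.integer(round(chg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Per-element imbalance of one reaction
#'
#' @param model a `gem_model`.
#' @param reaction_id reaction to inspect.
#' @return named numeric vector of element imbalances (products minus
#'   substrates), plus an attribute `charge` with the charge imbalance.
#' @export
reaction_imbalance <- function(model, reaction_id) {
  r <- model$reactions[[reaction_id]]
  if (is.null(r)) stop("unknown reaction: ", reaction_id)
  mets <- model$metabolites
  idx <- match(names(r$stoich), mets$id)
  total <- numeric(0)
  for (k in seq_along(idx)) {
    counts <- parse_formula(mets$formula[idx[k]])
    if (is.null(counts)) stop("metabolite ", mets$id[idx[k]], " has no formula")
    for (el in names(counts)) {
      total[el] <- (if (el %in% names(total)) total[[el]] else 0) +
        r$stoich[[k]] * counts[[el]]
    }
  }
  total <- total[abs(total) > 1e-9]
  attr(total, "charge") <- sum(r$stoich * mets$charge[idx])
  total
}

#' Find dead-end metabolites
#'
#' Using the directionality implied by the bounds (a reaction with `lb < 0`
#' can run backwards, so each of its metabolites is both producible and
#' consumable through it), a metabolite is a dead end when it appears in
#' exactly one reaction (`single_reaction`), can only be consumed
#' (`only_substrate`) or can only be produced (`only_product`). Each
#' compartmentalized metabolite is treated independently.
#'
#' @param model a `gem_model`.
#' @return data.frame `metabolite_id`, `category`; zero rows when the network
#'   is fully connected.
#' @export
find_dead_ends <- function(model) {
  mets <- metabolite_ids(model)
  n_rxn <- stats::setNames(integer(length(mets)), mets)
  producible <- stats::setNames(logical(length(mets)), mets)
  consumable <- stats::setNames(logical(length(mets)), mets)
  for (r in model$reactions) {
    fwd <- r$ub > GROWTH_TOL
    rev <- r$lb < -GROWTH_TOL
    for (k in seq_along(r$stoich)) {
      met <- names(r$stoich)[k]
      coef <- r$stoich[[k]]
      n_rxn[met] <- n_rxn[met] + 1L
      if ((coef > 0 && fwd) || (coef < 0 && rev)) producible[met] <- TRUE
      if ((coef < 0 && fwd) || (coef > 0 && rev)) consumable[met] <- TRUE
    }
  }
  cat_for <- function(met) {
    if (n_rxn[met] == 1L) return("single_reaction")
    if (producible[met] && !consumable[met]) return("only_product")
    if (consumable[met] && !producible[met]) return("only_substrate")
    NA_character_
  }
  cats <- vapply(mets, cat_for, character(1))
  dead <- !is.na(cats) | n_rxn[mets] == 0L
  out <- data.frame(metabolite_id = mets[dead],
                    category = ifelse(is.na(cats[dead]), "single_reaction", cats[dead]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect energy-generating cycles
#'
#' Closes every exchange lower bound to zero (no uptake) and maximizes each
#' designated energy-dissipation reaction (ATP/NADH/NADPH hydrolysis). In a
#' thermodynamically sane network nothing can be dissipated without substrate
#' input, so every maximum must be zero; a positive maximum reveals a futile
#' energy-generating cycle.
#'
#' @param model a `gem_model`.
#' @param dissipation_ids character vector of hydrolysis reaction ids.
#' @return named numeric vector of maximal dissipation fluxes; values above
#'   the growth tolerance flag a cycle. An infeasible closed model is
#'   reported as 0 (clean) with a warning.
#' @export
detect_energy_cycles <- function(model, dissipation_ids) {
  missing <- setdiff(dissipation_ids, reaction_ids(model))
  if (length(missing)) stop("unknown dissipation reaction(s): ",
                            paste(missing, collapse = ", "))
  closed <- model
  for (ex in exchange_ids(closed)) closed <- set_bounds(closed, ex, lb = 0)
  out <- stats::setNames(numeric(length(dissipation_ids)), dissipation_ids)
  for (id in dissipation_ids) {
    probe <- set_bounds(closed, id, ub = 1000)
    sol <- solve_fba(probe, objective_id = id, sense = "max")
    if (sol$status != "optimal") {
      warning("closed model infeasible while probing ", id, "; treated as clean")
      out[id] <- 0
    } else {
      out[id] <- sol$objective_value
    }
  }
  out
}

#' Unify duplicate metabolites and collapse duplicate reactions
#'
#' Rewrites deprecated metabolite ids to their canonical synonyms (same
#' compartment only), then collapses reactions left stoichiometrically
#' identical by the rewrite into one, keeping the union of their gene
#' associations under `or` and the widest bounds (with a warning when bounds
#' differed).
#'
#' @param model a `gem_model`.
#' @param synonym_table named character vector `deprecated id -> canonical id`.
#' @return the unified model.
#' @export
unify_duplicate_metabolites <- function(model, synonym_table) {
  if (length(synonym_table) == 0) return(model)
  for (i in seq_along(synonym_table)) {
    from <- names(synonym_table)[i]; to <- synonym_table[[i]]
    if (!identical(met_compartment(from), met_compartment(to))) {
      stop("cross-compartment synonym rejected: ", from, " -> ", to)
    }
  }
  keep <- !model$metabolites$id %in% names(synonym_table)
  missing <- setdiff(unname(synonym_table), model$metabolites$id)
  if (length(missing)) stop("canonical metabolite(s) not in model: ",
                            paste(missing, collapse = ", "))
  model$metabolites <- model$metabolites[keep, , drop = FALSE]
  for (id in names(model$reactions)) {
    st <- model$reactions[[id]]$stoich
    nm <- names(st)
    hit <- nm %in% names(synonym_table)
    nm[hit] <- unname(synonym_table[nm[hit]])
    # merge coefficients that now refer to the same metabolite
    st <- tapply(unname(st), nm, sum)
    st <- st[abs(st) > 1e-12]
    v <- as.numeric(st); names(v) <- names(st)
    model$reactions[[id]]$stoich <- v
  }
  # collapse reactions with identical stoichiometry
  sig <- vapply(model$reactions, function(r) {
    o <- order(names(r$stoich))
    paste(names(r$stoich)[o], format(r$stoich[o], digits = 12), collapse = ";")
  }, character(1))
  for (s in unique(sig[duplicated(sig)])) {
    ids <- names(sig)[sig == s]
    first <- ids[1]
    for (other in ids[-1]) {
      ra <- model$reactions[[first]]; rb <- model$reactions[[other]]
      if (ra$lb != rb$lb || ra$ub != rb$ub) {
        warning("collapsing '", other, "' into '", first,
                "' with differing bounds; keeping the widest")
      }
      model$reactions[[first]]$lb <- min(ra$lb, rb$lb)
      model$reactions[[first]]$ub <- max(ra$ub, rb$ub)
      model$reactions[[first]]$gpr <- gpr_or(ra$gpr, rb$gpr)
      model <- drop_reaction(model, other)
    }
  }
  model
}

#' Write QC reports as TSV
#'
#' @param balance data.frame from [check_mass_charge_balance()].
#' @param dead_ends data.frame from [find_dead_ends()].
#' @param dir output directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
write_qc_reports <- function(balance, dead_ends, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "balance_report.tsv")
  p2 <- file.path(dir, "dead_end_report.tsv")
  utils::write.table(balance, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dead_ends, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
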