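#' Filter homology hits by a parameter set
#'
#' A hit is retained iff `e_value <= max_e_value`, `alignment_length >=
#' min_query_length` and `identity >= min_identity`. The filter is monotone:
#' loosening any threshold never removes a retained hit.
#'
#' @param hits data.frame with columns `template_gene`, `target_gene`,
#'   `e_value`, `alignment_length`, `identity`, `bitscore` (extra columns are
#'   ignored).
#' @param params list with `max_e_value`, `min_query_length`, `min_identity`.
#' @return the retained subset of `hits`.
#' @export
filter_hits <- function(hits, params) {
  stopifnot(all(c("e_value", "alignment_length", "identity") %in% names(hits)))
  keep <- hits$e_value <= params$max_e_value &
    hits$alignment_length >= params$min_query_length &
    hits$identity >= params$min_identity
  hits[keep, , drop = FALSE]
}

#' Curation-replacement filter preset
#'
#' The stricter preset used when replacing exogenous proteins during manual
#' curation: e-value <= 1e-10 together with query coverage >= 75% and
#' identity >= 35%. Query coverage requires `query_length` alongside
#' `alignment_length`.
#'
#' @param hits hit table including a `query_length` column.
#' @return retained subset.
#' @export
filter_hits_curation <- function(hits) {
  stopifnot("query_length" %in% names(hits))
  keep <- hits$e_value <= 1e-10 &
    hits$alignment_length / hits$query_length >= 0.75 &
    hits$identity >= 35
  hits[keep, , drop = FALSE]
}

#' Best hit per template gene
#'
#' Deterministic one-to-one mapping: highest bitscore, ties broken by lower
#' e-value, then lexicographic target id.
#'
#' @param hits filtered hit table.
#' @return named character vector `template gene -> target gene`, with the
#'   supporting bitscore as attribute `"bitscore"`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) {
    out <- character(0); attr(out, "bitscore") <- numeric(0); return(out)
  }
  ord <- order(hits$template_gene, -hits$bitscore, hits$e_value, hits$target_gene)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$template_gene)
  out <- stats::setNames(h$target_gene[first], h$template_gene[first])
  attr(out, "bitscore") <- stats::setNames(h$bitscore[first], h$template_gene[first])
  out
}

#' Map template GPRs onto target genes
#'
#' Every template-gene leaf with a retained hit is replaced by its
#' best-bitscore target gene; reactions with at least one mapped leaf are
#' included in the candidate draft. Unmapped leaves are kept and flagged as
#' template genes (recorded in the draft's `template_genes` set for later
#' stripping). Each draft reaction records the best supporting bitscore, used
#' by [merge_drafts()] to resolve cross-template redundancy.
#'
#' @param template_model template `gem_model` with GPR rules.
#' @param hits retained hits (after [filter_hits()]).
#' @return a candidate draft: a `gem_model` whose reactions carry a
#'   `provenance` list (template id, best bitscore).
#' @export
map_gprs <- function(template_model, hits) {
  bh <- best_hits(hits)
  bs <- attr(bh, "bitscore")
  draft <- template_model
  draft$template_genes <- character(0)
  keep <- character(0)
  for (id in reaction_ids(template_model)) {
    r <- template_model$reactions[[id]]
    if (r$pseudo) { keep <- c(keep, id); next }
    genes <- gpr_genes(r$gpr)
    if (length(genes) == 0) { keep <- c(keep, id); next }
    mapped <- intersect(genes, names(bh))
    if (length(mapped) == 0) next  # no homology support: excluded from draft
    draft$reactions[[id]]$gpr <- gpr_substitute(r$gpr, bh[mapped])
    unmapped <- setdiff(genes, mapped)
    draft$template_genes <- union(draft$template_genes, unmapped)
    draft$reactions[[id]]$provenance <- list(
      template = template_model$id,
      bitscore = max(bs[mapped]))
    keep <- c(keep, id)
  }
  drop <- setdiff(reaction_ids(draft), keep)
  for (id in drop) draft <- drop_reaction(draft, id)
  # prune metabolites no longer referenced
  used <- unique(unlist(lapply(draft$reactions, function(r) names(r$stoich))))
  draft$metabolites <- draft$metabolites[draft$metabolites$id %in% used, , drop = FALSE]
  draft
}

#' Default calibration grid
#'
#' Four e-values, six alignment lengths (50-200 aa) and six identity
#' percentages (20-50%): 144 parameter combinations.
#'
#' @return data.frame of 144 rows (`max_e_value`, `min_query_length`,
#'   `min_identity`).
#' @export
default_blast_grid <- function() {
  expand.grid(max_e_value = c(1e-30, 1e-20, 1e-10, 1e-5),
              min_query_length = c(50, 80, 100, 120, 150, 200),
              min_identity = c(20, 25, 30, 35, 40, 50),
              KEEP.OUT.ATTRS = FALSE)
}

gold_gene_sets <- function(gold) {
  sets <- lapply(gold$gpr_string, function(s) gpr_genes(gpr_parse(s)))
  names(sets) <- gold$reaction_id
  sets
}

#' Grid search over homology-filter parameters
#'
#' Evaluates every parameter combination against a curated gold set of
#' gene-reaction assignments. For each cell the retained hits are reduced to
#' best hits, and each gold reaction's template GPR genes are compared with
#' the curated genes: a mapped target gene that is in the curated rule is a
#' true positive, one that is not is a false positive; curated genes never
#' proposed are false negatives; the remaining pairs over the gold-set gene
#' universe are true negatives. The optimum maximizes F1, ties broken by
#' fewer retained template genes, then by stricter e-value.
#'
#' @param hits full hit table.
#' @param template_model template `gem_model` (supplies the template GPRs the
#'   assignments are projected through).
#' @param gold data.frame `reaction_id`, `gpr_string` (curated truth).
#' @param grid data.frame of parameter combinations; defaults to
#'   [default_blast_grid()].
#' @return list with `results` (one row per cell: parameters, TP/FP/TN/FN,
#'   precision, recall, F1, n_template_genes_retained) and `optimum` (the
#'   selected row).
#' @export
grid_search <- function(hits, template_model, gold, grid = default_blast_grid()) {
  if (is.null(gold) || nrow(gold) == 0) stop("gold set is empty")
  stopifnot(nrow(grid) > 0)
  gold_sets <- gold_gene_sets(gold)
  universe <- sort(unique(unlist(gold_sets)))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, ])
    retained <- filter_hits(hits, params)
    bh <- best_hits(retained)
    tp <- fp <- tn <- fn <- 0L
    for (rid in names(gold_sets)) {
      r <- template_model$reactions[[rid]]
      tmpl_genes <- if (is.null(r)) character(0) else gpr_genes(r$gpr)
      proposed <- unname(bh[intersect(tmpl_genes, names(bh))])
      truth <- gold_sets[[rid]]
      tp <- tp + length(intersect(proposed, truth))
      fp <- fp + length(setdiff(proposed, truth))
      fn <- fn + length(setdiff(truth, proposed))
      tn <- tn + length(setdiff(universe, union(proposed, truth)))
    }
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    rows[[i]] <- data.frame(
      max_e_value = params$max_e_value,
      min_query_length = params$min_query_length,
      min_identity = params$min_identity,
      TP = tp, FP = fp, TN = tn, FN = fn,
      precision = precision, recall = recall, F1 = f1,
      n_template_genes_retained = length(unique(retained$template_gene)))
  }
  results <- do.call(rbind, rows)
  ord <- order(-results$F1, results$n_template_genes_retained,
               results$max_e_value)
  list(results = results, optimum = results[ord[1], ])
}

#' Merge candidate drafts from several templates
#'
#' Reactions present in multiple drafts appear once, taking GPR and
#' provenance from the draft whose supporting hit has the highest bitscore;
#' metabolites are unioned; template-flagged genes are preserved for
#' [strip_template_genes()]. A reaction id appearing with different
#' stoichiometry in two drafts is an error listing both.
#'
#' @param drafts list of candidate drafts from [map_gprs()].
#' @return merged `gem_model`.
#' @export
merge_drafts <- function(drafts) {
  stopifnot(length(drafts) >= 1)
  merged <- gem_model(id = "merged_draft")
  for (d in drafts) {
    for (i in seq_len(nrow(d$metabolites))) {
      mm <- d$metabolites[i, ]
      if (!mm$id %in% merged$metabolites$id) {
        merged <- add_metabolite(merged, mm$id, mm$name, mm$formula,
                                 mm$charge, mm$compartment)
      }
    }
    merged$template_genes <- union(merged$template_genes, d$template_genes)
    for (id in reaction_ids(d)) {
      r <- d$reactions[[id]]
      if (!id %in% reaction_ids(merged)) {
        merged$reactions[[id]] <- r
        next
      }
      old <- merged$reactions[[id]]
      same <- length(old$stoich) == length(r$stoich) &&
        setequal(names(old$stoich), names(r$stoich)) &&
        all(abs(old$stoich[names(r$stoich)] - r$stoich) < 1e-9)
      if (!same) {
        stop("stoichiometry conflict for reaction '", id, "' between drafts '",
             old$provenance$template %||% "?", "' and '",
             r$provenance$template %||% "?", "'")
      }
      old_bs <- old$provenance$bitscore %||% -Inf
      new_bs <- r$provenance$bitscore %||% -Inf
      if (new_bs > old_bs) merged$reactions[[id]] <- r
    }
  }
  if (length(drafts) > 0 && !is.na(drafts[[1]]$objective) &&
      drafts[[1]]$objective %in% reaction_ids(merged)) {
    merged$objective <- drafts[[1]]$objective
  }
  merged
}

#' Strip template genes from a merged draft
#'
#' Removes leaves flagged as template genes from every GPR rule: `or`
#' branches are pruned (an isozyme alternative is simply lost) while an `and`
#' branch containing a flagged leaf collapses, orphaning the reaction, which
#' is then flagged for curation.
#'
#' @param model merged draft with a `template_genes` set.
#' @return list with `model` (stripped) and `report` (data.frame
#'   `reaction_id`, `outcome` in `pruned`/`orphaned` for every affected
#'   reaction).
#' @export
strip_template_genes <- function(model) {
  flagged <- model$template_genes
  report <- list()
  for (id in reaction_ids(model)) {
    r <- model$reactions[[id]]
    if (is.null(r$gpr)) next
    genes <- gpr_genes(r$gpr)
    if (!any(genes %in% flagged)) next
    pruned <- gpr_prune(r$gpr, flagged)
    model$reactions[[id]]$gpr <- pruned
    report[[id]] <- data.frame(
      reaction_id = id,
      outcome = if (is.null(pruned)) "orphaned" else "pruned",
      stringsAsFactors = FALSE)
  }
  model$template_genes <- character(0)
  rep_df <- if (length(report)) do.call(rbind, report) else
    data.frame(reaction_id = character(0), outcome = character(0))
  rownames(rep_df) <- NULL
  list(model = model, report = rep_df)
}

#' Read a homology hit table from TSV
#'
#' Expects at least the six canonical columns (`template_gene`,
#' `target_gene`, `e_value`, `alignment_length`, `identity`, `bitscore`);
#' extra columns from tabular alignment output are carried along.
#'
#' @param path TSV file.
#' @return data.frame of hits.
#' @export
read_hit_table <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("template_gene", "target_gene", "e_value", "alignment_length",
            "identity", "bitscore")
  missing <- setdiff(need, names(h))
  if (length(missing)) stop("hit table misses column(s): ",
                            paste(missing, collapse = ", "))
  h
}
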