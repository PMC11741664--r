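#' Predict growth over a phenotype panel
#'
#' Runs FBA per condition, makes a qualitative growth call (growth iff the
#' predicted rate exceeds the growth tolerance) and tallies the confusion
#' against the experimental table. Conditions whose substrate has no exchange
#' reaction in the model are excluded and reported rather than failing — the
#' situation of Biolog wells that cannot be mapped to the network.
#'
#' @param model a `gem_model`.
#' @param conditions named list of [growth_condition()] objects.
#' @param experimental data.frame `condition_id`, `substrate_id`, `growth`
#'   (0/1), `class` (`high`/`medium`/`low`/`NA`).
#' @return list with `calls` (per-condition data.frame: condition_id,
#'   predicted_mu, predicted_growth, experimental_growth, call,
#'   experimental_class), `summary` (accuracy, sensitivity, ppv and the four
#'   cells; `NA` when a denominator is zero) and `excluded` (unmappable
#'   condition ids).
#' @export
predict_growth_panel <- function(model, conditions, experimental) {
  stopifnot(is.list(conditions))
  exps <- stats::setNames(experimental$growth, experimental$condition_id)
  cls <- stats::setNames(experimental$class, experimental$condition_id)
  rows <- list(); excluded <- character(0)
  for (cid in names(conditions)) {
    cond <- conditions[[cid]]
    mappable <- all(vapply(c(names(cond$carbon), names(cond$nitrogen)),
                           function(b) paste0("EX_", b, "_e") %in% reaction_ids(model),
                           logical(1)))
    if (!mappable) { excluded <- c(excluded, cid); next }
    sol <- solve_fba(apply_condition(model, cond))
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    pred <- mu > GROWTH_TOL
    expg <- as.logical(exps[cid])
    call <- if (is.na(expg)) NA_character_
            else if (pred && expg) "TP" else if (!pred && !expg) "TN"
            else if (pred && !expg) "FP" else "FN"
    rows[[cid]] <- data.frame(
      condition_id = cid, predicted_mu = mu, predicted_growth = pred,
      experimental_growth = expg, call = call,
      experimental_class = if (cid %in% names(cls)) cls[[cid]] else NA_character_,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  tab <- table(factor(calls$call, levels = c("TP", "TN", "FP", "FN")))
  n <- sum(tab)
  s <- list(TP = unname(tab["TP"]), TN = unname(tab["TN"]),
            FP = unname(tab["FP"]), FN = unname(tab["FN"]),
            n = n,
            accuracy = if (n > 0) unname(tab["TP"] + tab["TN"]) / n else NA_real_,
            sensitivity = if (tab["TP"] + tab["FN"] > 0)
              unname(tab["TP"] / (tab["TP"] + tab["FN"])) else NA_real_,
            ppv = if (tab["TP"] + tab["FP"] > 0)
              unname(tab["TP"] / (tab["TP"] + tab["FP"])) else NA_real_)
  list(calls = calls, summary = s, excluded = excluded)
}

#' Classify predicted growth into high/medium/low
#'
#' Experimental growth levels come as three ordered categories. The predicted
#' rates of the true-positive conditions are z-scored and mapped to the same
#' three categories by rank quantiles chosen so the predicted class counts
#' equal the experimental class counts — the mapping the experimental
#' marginals impose, since no absolute category thresholds exist for a
#' simulated growth rate. The mapping is therefore invariant under any
#' strictly monotone transform of the predicted rates. Ties are broken by
#' condition id for determinism. Each condition's outcome is `correct`,
#' `under` (model predicts a lower category) or `over`.
#'
#' @param calls `calls` data.frame from [predict_growth_panel()]; rows with
#'   call `"TP"` and a non-`NA` experimental class participate.
#' @return `calls` with `predicted_class`, `class_outcome` and
#'   `predicted_mu_z` columns added (non-participating rows get `NA`).
#'   With fewer than 3 eligible conditions the classification is skipped
#'   with a message.
#' @export
classify_growth_levels <- function(calls) {
  lev <- c("low", "medium", "high")
  calls$predicted_class <- NA_character_
  calls$class_outcome <- NA_character_
  calls$predicted_mu_z <- NA_real_
  idx <- which(calls$call == "TP" & !is.na(calls$experimental_class))
  if (length(idx) < 3) {
    message("fewer than 3 true-positive conditions with classes; classification skipped")
    return(calls)
  }
  mu <- calls$predicted_mu[idx]
  z <- if (stats::sd(mu) > 0) (mu - mean(mu)) / stats::sd(mu) else rep(0, length(mu))
  calls$predicted_mu_z[idx] <- z
  counts <- table(factor(calls$experimental_class[idx], levels = lev))
  ord <- idx[order(calls$predicted_mu[idx], calls$condition_id[idx])]
  assigned <- rep(lev, times = counts)   # ascending: low block first
  calls$predicted_class[ord] <- assigned
  ei <- match(calls$experimental_class[idx], lev)
  pi_ <- match(calls$predicted_class[idx], lev)
  calls$class_outcome[idx] <- ifelse(pi_ == ei, "correct",
                                     ifelse(pi_ < ei, "under", "over"))
  calls
}

#' Total flux activity per subsystem and condition
#'
#' Activity of a subsystem in a condition is the sum of absolute fluxes over
#' its member reactions. Subsystems inactive in every condition are dropped;
#' the remainder is z-scored per subsystem across conditions (zero-variance
#' subsystems get all-zero scores).
#'
#' @param model a `gem_model`.
#' @param solutions named list of `gemflux_fba` solutions (one per condition).
#' @return list with `activity` and `zscores`, both matrices
#'   conditions x subsystems.
#' @export
subsystem_activity <- function(model, solutions) {
  subs <- vapply(model$reactions, function(r) r$subsystem, character(1))
  sublevels <- sort(unique(subs[nzchar(subs)]))
  conds <- names(solutions)
  act <- matrix(0, length(conds), length(sublevels),
                dimnames = list(conds, sublevels))
  for (ci in seq_along(conds)) {
    sol <- solutions[[ci]]
    if (is.null(sol$fluxes)) next
    v <- abs(sol$fluxes)
    for (si in seq_along(sublevels)) {
      member <- names(subs)[subs == sublevels[si]]
      act[ci, si] <- sum(v[member], na.rm = TRUE)
    }
  }
  keep <- colSums(act > GROWTH_TOL) > 0
  act <- act[, keep, drop = FALSE]
  z <- apply(act, 2, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(act), dimnames = dimnames(act))
  list(activity = act, zscores = z)
}
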