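# Independent oracles used to cross-check the package's own algorithms.
# These deliberately avoid the code paths they verify.

# Brute-force LP oracle: enumerate candidate vertices (n - rank(A) variables
# pinned at a bound, the rest solved from the square equality system) and
# take the best feasible objective.
brute_force_lp <- function(obj, A, b, lb, ub) {
  A <- as.matrix(A); n <- ncol(A)
  qrA <- qr(t(A))
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  m <- nrow(A); nf <- n - m
  best <- -Inf; found <- FALSE
  combos <- if (nf == 0) list(integer(0)) else utils::combn(n, nf, simplify = FALSE)
  for (fix in combos) {
    freev <- setdiff(seq_len(n), fix)
    B <- A[, freev, drop = FALSE]
    if (length(freev) && abs(det(B)) < 1e-10) next
    grids <- if (length(fix)) expand.grid(rep(list(c(1, 2)), length(fix)))
             else data.frame(row.names = 1)
    for (g in seq_len(nrow(grids))) {
      x <- numeric(n)
      if (length(fix)) x[fix] <- ifelse(unlist(grids[g, ]) == 1, lb[fix], ub[fix])
      rhs <- b - if (length(fix)) A[, fix, drop = FALSE] %*% x[fix] else 0 * b
      if (length(freev)) x[freev] <- solve(B, rhs)
      if (all(x >= lb - 1e-7) && all(x <= ub + 1e-7) &&
          max(abs(A %*% x - b)) < 1e-7) {
        found <- TRUE
        best <- max(best, sum(obj * x))
      }
    }
  }
  list(found = found, objective = best)
}

fba_oracle <- function(model, objective_id = model$objective) {
  parts <- gemflux:::model_lp_parts(model)
  obj <- as.numeric(reaction_ids(model) == objective_id)
  brute_force_lp(obj, parts$S, parts$b, parts$lb, parts$ub)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    rx <- rank(pooled)[ix]
    sum(rx) - nx * (nx + 1) / 2
  }
  u_obs <- u_stat(seq_len(nx))
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx, simplify = FALSE)
  us <- vapply(combos, u_stat, numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exhaustive deletion oracle: re-solve every knockout without the zero-flux
# shortcut the screens use.
exhaustive_deletion <- function(model, conditions, by = "gene") {
  entities <- if (by == "gene") model_genes(model) else {
    ids <- reaction_ids(model)
    ids[!vapply(model$reactions, function(r) r$pseudo, logical(1))]
  }
  rows <- list()
  for (cid in names(conditions)) {
    constrained <- apply_condition(model, conditions[[cid]])
    wt <- solve_fba(constrained)$objective_value
    for (ent in entities) {
      disabled <- if (by == "gene") {
        hit <- vapply(model$reactions, function(r) {
          !is.null(r$gpr) && !gpr_eval(r$gpr, ent)
        }, logical(1))
        names(hit)[hit]
      } else ent
      kom <- constrained
      for (rid in disabled) kom <- set_bounds(kom, rid, lb = 0, ub = 0)
      sol <- solve_fba(kom)
      ko <- if (sol$status == "optimal") sol$objective_value else 0
      ratio <- ko / wt
      if (ratio > 1 && ratio <= 1 + 1e-6) ratio <- 1
      cls <- if (ratio >= 1 - 1e-6) "non_essential"
             else if (ko <= 1e-6) "lethal" else "growth_reducing"
      rows[[length(rows) + 1]] <- data.frame(entity = ent, condition = cid,
                                             class = cls)
    }
  }
  do.call(rbind, rows)
}

toy_conditions <- function() {
  list(ac_aer = condition_acetate_aerobic(),
       ac_ana = condition_acetate_anaerobic(),
       bz_aer = condition_substrate("bz", 10, TRUE),
       bz_ana = condition_substrate("bz", 10, FALSE),
       pyr_aer = condition_substrate("pyr", 10, TRUE))
}

rich_condition <- function() {
  growth_condition("rich",
                   carbon = c(ac = 10, pyr = 10, bz = 10, ala__L = 10,
                              ser__L = 10, `for` = 10),
                   nitrogen = c(nh4 = Inf, no3 = Inf),
                   aerobic = TRUE, minerals = c("pi", "h2o"))
}
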