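# Internal linear-programming layer.
#
# Solves  max/min c'v  s.t.  A v = b,  lb <= v <= ub  with the bounded-
# variable revised simplex in simplex.R. Bounds are always finite (the
# engine caps unspecified bounds at +/-1000), so the LP can never be
# unbounded; the only non-optimal outcome is infeasibility.

LP_FEAS_TOL <- 1e-9
LP_REPORT_TOL <- 1e-6

solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(lb) == n, length(ub) == n, nrow(A) == length(b))
  A <- as.matrix(A)
  if (any(ub - lb < -LP_FEAS_TOL)) {
    return(list(status = "infeasible", objective = NA_real_, fluxes = NULL))
  }
  # drop linearly dependent equality rows (conserved moieties make metabolite
  # balances rank-deficient); consistency of the dropped rows is checked on
  # the solution
  qrA <- qr(t(A))
  keep <- seq_len(nrow(A))
  if (qrA$rank < nrow(A)) keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  res <- simplex_bounded(if (maximize) obj else -obj,
                         A[keep, , drop = FALSE], b[keep], lb, ub)
  if (!identical(res$status, "optimal")) {
    return(list(status = "infeasible", objective = NA_real_, fluxes = NULL))
  }
  v <- res$x
  if (max(abs(A %*% v - b)) > 1e-6) {
    return(list(status = "infeasible", objective = NA_real_, fluxes = NULL))
  }
  names(v) <- colnames(A)
  list(status = "optimal", objective = sum(obj * v), fluxes = v)
}

# Constraint system of a model: equality rows are the metabolite mass
# balances plus any coupling rows (e.g. polymer/biomass mass coupling).
model_lp_parts <- function(model) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  b <- rep(0, nrow(S))
  if (length(model$couplings) > 0) {
    for (cp in model$couplings) {
      row <- rep(0, ncol(S))
      idx <- match(names(cp$coef), colnames(S))
      if (anyNA(idx)) stop("coupling references unknown reaction(s)")
      row[idx] <- unname(cp$coef)
      S <- rbind(S, row)
      b <- c(b, cp$rhs)
    }
  }
  lb <- vapply(model$reactions, function(r) max(r$lb, -1000), numeric(1))
  ub <- vapply(model$reactions, function(r) min(r$ub, 1000), numeric(1))
  list(S = S, b = b, lb = lb, ub = ub)
}
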