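# Bounded-variable revised simplex with Bland's rule.
#
# Solves  max c'x  s.t.  A x = b,  l <= x <= u  with A of full row rank.
# Two-phase: phase 1 minimizes the sum of artificial variables from a
# bound-valued start; phase 2 optimizes the real objective. Bland's smallest-
# index pivoting guarantees termination on the degenerate bases that
# metabolic networks produce (conserved moieties, parallel routes). Problem
# sizes here are tens of rows, so bases are refactorized by dense solves.

simplex_bounded <- function(cvec, A, b, lb, ub, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cvec) == n, length(lb) == n, length(ub) == n, length(b) == m)
  if (any(lb > ub + tol)) return(list(status = "infeasible"))
  if (m == 0L) {
    x <- ifelse(cvec > 0, ub, lb)
    return(list(status = "optimal", x = x, objective = sum(cvec * x)))
  }
  # start: structural variables at the finite bound closest to zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  r <- b - as.numeric(A %*% x)
  # artificial columns absorb the residual
  Afull <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  big <- sum(abs(r)) + 1
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(big, m))
  xf <- c(x, abs(r))
  basis <- n + seq_len(m)
  at_upper <- logical(n + m)   # nonbasic position: FALSE = lower, TRUE = upper
  at_upper[seq_len(n)] <- abs(lb) > abs(ub)

  run_phase <- function(cost, basis, xf, at_upper, phase1) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit"))
      B <- Afull[, basis, drop = FALSE]
      Binv_ok <- TRUE
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) { Binv_ok <<- FALSE; NULL })
      if (!Binv_ok) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(n + m), basis)
      d <- cost[nonbasic] - as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))
      fixed <- ubf[nonbasic] - lbf[nonbasic] <= tol
      improving <- !fixed & ((d > tol & !at_upper[nonbasic]) |
                             (d < -tol & at_upper[nonbasic]))
      if (!any(improving)) {
        return(list(status = "optimal", basis = basis, xf = xf,
                    at_upper = at_upper))
      }
      j <- nonbasic[improving][which.min(nonbasic[improving])]  # Bland
      dir <- if (at_upper[j]) -1 else 1                          # x_j moves by dir * t
      w <- solve(B, Afull[, j])                                  # basic change: -dir * w * t
      # ratio test: how far can x_j move before something hits a bound
      xb <- xf[basis]
      delta <- -dir * w                        # rate of change of basic vars
      lim <- rep(Inf, m); to_upper <- logical(m)
      up <- delta > tol                        # basic var rising toward ub
      dn <- delta < -tol                       # basic var falling toward lb
      lim[up] <- (ubf[basis[up]] - xb[up]) / delta[up]
      to_upper[up] <- TRUE
      lim[dn] <- (lbf[basis[dn]] - xb[dn]) / delta[dn]
      lim <- pmax(lim, 0)
      t_flip <- ubf[j] - lbf[j]                # entering var reaches other bound
      t_max <- min(t_flip, min(lim))
      if (!is.finite(t_max)) return(list(status = "unbounded"))
      # apply the step
      xf[j] <- xf[j] + dir * t_max
      xf[basis] <- xf[basis] + delta * t_max
      if (t_flip <= min(lim) + tol) {
        at_upper[j] <- !at_upper[j]     # entering variable flipped bounds
      } else {
        blocking <- which(lim <= t_max + tol)
        leave <- blocking[which.min(basis[blocking])]    # Bland
        lv <- basis[leave]
        at_upper[lv] <- to_upper[leave]
        xf[lv] <- if (to_upper[leave]) ubf[lv] else lbf[lv]
        basis[leave] <- j
      }
    }
  }

  # phase 1: minimize sum of artificials (= maximize the negative sum)
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, basis, xf, at_upper, phase1 = TRUE)
  if (!identical(ph1$status, "optimal")) return(list(status = "infeasible"))
  if (sum(ph1$xf[n + seq_len(m)]) > 1e-6) return(list(status = "infeasible"))
  # freeze artificials at zero and optimize the real objective
  ubf[n + seq_len(m)] <- 0
  xf <- ph1$xf; xf[n + seq_len(m)] <- 0
  ph2 <- run_phase(c(cvec, rep(0, m)), ph1$basis, xf, ph1$at_upper, phase1 = FALSE)
  if (identical(ph2$status, "unbounded")) return(list(status = "unbounded"))
  if (!identical(ph2$status, "optimal")) return(list(status = "infeasible"))
  x <- ph2$xf[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, objective = sum(cvec * x))
}
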