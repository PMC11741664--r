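#' Artificial-centering hit-and-run flux sampling
#'
#' Samples the steady-state flux polytope `{v : S v = 0, lb <= v <= ub}` of a
#' model, typically after [fix_optimum_and_constrain()] so the walk explores
#' the optimal face. Warmup points are polytope corners obtained by
#' maximizing and minimizing random sparse objectives; the walk then repeats:
#' pick a stored warmup point, take the direction from the running center
#' (the mean of all visited points) to it, project it onto the null space of
#' the constraint matrix, and jump to a uniform point on the feasible segment
#' through the current point. The current point is tracked in null-space
#' coordinates, so `S v = 0` holds to machine precision at every step instead
#' of drifting. Reactions whose feasible range is degenerate are held fixed
#' and sampling proceeds in the remaining dimensions.
#'
#' @param model a `gem_model` (pin the objective first for sampling at
#'   optimal growth).
#' @param n_samples number of samples to keep (rows).
#' @param seed RNG seed; identical seeds give bit-identical sample matrices.
#' @param thinning steps between kept samples.
#' @param n_warmup number of warmup corners; default `2 *` free dimensions.
#' @param condition_id label stored with the sample.
#' @return a `gemflux_sample`: list with `points` (n_samples x n_reactions
#'   matrix), `condition_id`, `seed`, `n_samples`.
#' @export
achr_sample <- function(model, n_samples = 5000, seed = 1L, thinning = 100,
                        n_warmup = NULL, condition_id = model$id) {
  set.seed(seed)
  parts <- model_lp_parts(model)
  S <- parts$S; lb <- parts$lb; ub <- parts$ub
  n <- ncol(S)
  rxns <- reaction_ids(model)
  # null-space basis of the full constraint matrix
  N <- null_space(S)
  if (ncol(N) == 0) {
    sol <- solve_fba(model)
    if (sol$status != "optimal") stop("model infeasible; cannot sample")
    pts <- matrix(rep(sol$fluxes, n_samples), nrow = n_samples, byrow = TRUE,
                  dimnames = list(NULL, rxns))
    return(structure(list(points = pts, condition_id = condition_id,
                          seed = seed, n_samples = n_samples),
                     class = "gemflux_sample"))
  }
  if (is.null(n_warmup)) n_warmup <- max(2L * ncol(N), 10L)
  # warmup corners: optimize random sparse +/-1 objectives
  warm <- matrix(NA_real_, n_warmup, n)
  k <- 0L; tries <- 0L
  while (k < n_warmup && tries < 10L * n_warmup) {
    tries <- tries + 1L
    obj <- numeric(n)
    nz <- sample(n, min(n, sample(1:3, 1)))
    obj[nz] <- sample(c(-1, 1), length(nz), replace = TRUE)
    res <- solve_lp(obj, S, parts$b, lb, ub, maximize = TRUE)
    if (res$status == "optimal") { k <- k + 1L; warm[k, ] <- res$fluxes }
  }
  if (k < 2L) stop("could not generate warmup points; model may be infeasible")
  warm <- warm[seq_len(k), , drop = FALSE]
  x0 <- colMeans(warm)
  # represent states as x0 + N z ; express warmup points in z-coordinates
  Wz <- (warm - matrix(x0, k, n, byrow = TRUE)) %*% N
  center_z <- colMeans(Wz)
  z <- center_z
  n_visited <- 1
  eps <- 1e-12
  pts <- matrix(NA_real_, n_samples, n, dimnames = list(NULL, rxns))
  NT <- t(N)
  for (s in seq_len(n_samples)) {
    for (step in seq_len(thinning)) {
      w <- Wz[sample.int(k, 1L), ]
      dz <- w - center_z
      nd <- sqrt(sum(dz^2))
      if (nd < eps) next
      dz <- dz / nd
      u <- as.numeric(N %*% dz)          # direction in flux space
      x <- x0 + as.numeric(N %*% z)
      pos <- u > 1e-9; neg <- u < -1e-9
      amax <- suppressWarnings(min(c((ub[pos] - x[pos]) / u[pos],
                                     (lb[neg] - x[neg]) / u[neg])))
      amin <- suppressWarnings(max(c((lb[pos] - x[pos]) / u[pos],
                                     (ub[neg] - x[neg]) / u[neg])))
      if (!is.finite(amax) || !is.finite(amin) || amax <= amin) next
      alpha <- stats::runif(1, amin, amax)
      z <- z + alpha * dz
      n_visited <- n_visited + 1
      center_z <- center_z + (z - center_z) / n_visited
    }
    x <- x0 + as.numeric(N %*% z)
    pts[s, ] <- pmin(pmax(x, lb), ub)   # clip fp dust at the boundary
  }
  structure(list(points = pts, condition_id = condition_id, seed = seed,
                 n_samples = n_samples),
            class = "gemflux_sample")
}

null_space <- function(S) {
  S <- as.matrix(S)
  sv <- svd(S, nu = 0, nv = ncol(S))
  tol <- max(dim(S)) * max(sv$d, 0) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank == ncol(S)) return(matrix(0, ncol(S), 0))
  sv$v[, (rank + 1):ncol(S), drop = FALSE]
}

#' @export
print.gemflux_sample <- function(x, ...) {
  cat("ACHR sample: ", nrow(x$points), " points x ", ncol(x$points),
      " reactions (condition ", x$condition_id, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test (wrapper)
#'
#' Two-sided rank-sum test via [stats::wilcox.test()], exact for small
#' tie-free samples and normal-approximated otherwise, returning the U
#' statistic of `x` and the p-value.
#'
#' @param x,y numeric vectors.
#' @return list with `U`, `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = length(x) + length(y) <= 50))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Subsystem up/down-regulation between two flux samples
#'
#' For each subsystem, per-sample activity is the sum of absolute fluxes over
#' its member reactions; the two resulting activity distributions (condition
#' vs reference, e.g. an aromatic substrate vs acetate) are compared with a
#' two-sided Mann-Whitney U test. Direction is the sign of the median
#' difference (`up` = condition median above reference). Subsystems with zero
#' activity in both samples are skipped; results are filtered at `alpha`
#' before reporting.
#'
#' @param sample_condition,sample_reference `gemflux_sample` objects over the
#'   same model topology (identical reaction columns).
#' @param model the `gem_model` supplying subsystem membership.
#' @param alpha p-value threshold for reporting (default 0.05; set to 1 to
#'   keep everything).
#' @return data.frame `subsystem`, `U`, `p_value`, `minus_log10_p`,
#'   `direction` (`up`/`down`/`none`), `median_condition`,
#'   `median_reference`, sorted by p-value.
#' @export
subsystem_regulation <- function(sample_condition, sample_reference, model,
                                 alpha = 0.05) {
  stopifnot(identical(colnames(sample_condition$points),
                      colnames(sample_reference$points)))
  subs <- vapply(model$reactions, function(r) r$subsystem, character(1))
  sublevels <- sort(unique(subs[nzchar(subs)]))
  rows <- list()
  for (ss in sublevels) {
    member <- names(subs)[subs == ss]
    a <- rowSums(abs(sample_condition$points[, member, drop = FALSE]))
    b <- rowSums(abs(sample_reference$points[, member, drop = FALSE]))
    if (max(a) <= GROWTH_TOL && max(b) <= GROWTH_TOL) next
    mw <- mann_whitney_u(a, b)
    # two constant equal distributions leave the normal approximation 0/0;
    # that is "no evidence of a shift", i.e. p = 1
    if (is.na(mw$p_value)) mw$p_value <- 1
    # p underflows to 0 for huge samples; floor it so -log10 stays finite
    mw$p_value <- max(mw$p_value, 1e-300)
    med_d <- stats::median(a) - stats::median(b)
    rows[[ss]] <- data.frame(
      subsystem = ss, U = mw$U, p_value = mw$p_value,
      minus_log10_p = -log10(mw$p_value),
      direction = if (abs(med_d) <= 1e-12) "none" else if (med_d > 0) "up" else "down",
      median_condition = stats::median(a), median_reference = stats::median(b),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(subsystem = character(0), U = numeric(0),
                      p_value = numeric(0), minus_log10_p = numeric(0),
                      direction = character(0), median_condition = numeric(0),
                      median_reference = numeric(0)))
  }
  out <- out[out$p_value <= alpha, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Verify a flux sample against the model constraints
#'
#' @param sample a `gemflux_sample`.
#' @param model the sampled `gem_model`.
#' @param tol feasibility tolerance.
#' @return fraction of rows satisfying both `S v = 0` and the bounds within
#'   `tol`.
#' @export
sample_feasibility <- function(sample, model, tol = 1e-6) {
  parts <- model_lp_parts(model)
  resid <- abs(sample$points %*% t(parts$S))
  ok_s <- apply(resid, 1, max) <= tol
  lbm <- matrix(parts$lb, nrow(sample$points), ncol(sample$points), byrow = TRUE)
  ubm <- matrix(parts$ub, nrow(sample$points), ncol(sample$points), byrow = TRUE)
  ok_b <- apply(sample$points >= lbm - tol & sample$points <= ubm + tol, 1, all)
  mean(ok_s & ok_b)
}
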