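#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux through an objective reaction subject to
#' steady state (`S v = 0`) and the flux bounds. Only the objective value is a
#' contract of the method: the flux vector returned is one of possibly many
#' alternate optima.
#'
#' @param model a `gem_model`.
#' @param objective_id reaction to optimize; defaults to the model objective.
#' @param sense `"max"` or `"min"`.
#' @return a `gemflux_fba` list with `status` (`"optimal"`/`"infeasible"`),
#'   `objective_value` (growth rate in 1/h when the objective is biomass) and
#'   `fluxes` (named vector, `NULL` unless optimal). Infeasibility is reported
#'   in `status`, never thrown.
#' @examples
#' m <- make_toy_model()
#' sol <- solve_fba(apply_condition(m, condition_acetate_aerobic()))
#' sol$objective_value
#' @export
solve_fba <- function(model, objective_id = model$objective, sense = "max") {
  stopifnot(inherits(model, "gem_model"))
  if (is.na(objective_id) || !objective_id %in% reaction_ids(model)) {
    stop("objective reaction '", objective_id, "' not in model")
  }
  parts <- model_lp_parts(model)
  obj <- as.numeric(reaction_ids(model) == objective_id)
  res <- solve_lp(obj, parts$S, parts$b, parts$lb, parts$ub,
                  maximize = identical(sense, "max"))
  structure(list(status = res$status,
                 objective_value = res$objective,
                 fluxes = res$fluxes,
                 objective_id = objective_id),
            class = "gemflux_fba")
}

#' @export
print.gemflux_fba <- function(x, ...) {
  cat("FBA solution [", x$status, "] objective ", x$objective_id, " = ",
      format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Growth-call threshold
#'
#' One epsilon is used everywhere a flux is compared with zero: growth calls,
#' essentiality classes, energy-cycle detection and producibility tests.
#' @export
GROWTH_TOL <- 1e-6

#' Test whether a metabolite can be produced
#'
#' Temporarily adds an export sink for the metabolite and maximizes it under
#' the given (rich) condition; the model is left untouched.
#'
#' @param model a `gem_model`, typically after [apply_condition()] with a rich
#'   medium.
#' @param metabolite_id metabolite to test.
#' @return `TRUE` iff the maximal sink flux exceeds the growth tolerance.
#' @export
sink_producibility <- function(model, metabolite_id) {
  if (!metabolite_id %in% metabolite_ids(model)) {
    stop("unknown metabolite: ", metabolite_id)
  }
  sink_id <- paste0("SK_gemflux_probe_", metabolite_id)
  st <- c(-1); names(st) <- metabolite_id
  probe <- add_reaction(model, sink_id, st, lb = 0, ub = 1000, pseudo = TRUE)
  sol <- solve_fba(probe, objective_id = sink_id, sense = "max")
  sol$status == "optimal" && sol$objective_value > GROWTH_TOL
}

#' Pin the objective at (a fraction of) its optimum
#'
#' Solves FBA, then fixes the objective reaction's bounds to
#' `[fraction * mu_star, mu_star]`. Used before flux sampling and polymer
#' analyses so downstream computations explore the optimal (or near-optimal)
#' face of the flux polytope.
#'
#' @param model a `gem_model`.
#' @param objective_id reaction to pin; defaults to the model objective.
#' @param fraction number in (0, 1]; 1 pins the objective exactly.
#' @return the constrained model.
#' @export
fix_optimum_and_constrain <- function(model, objective_id = model$objective,
                                      fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  sol <- solve_fba(model, objective_id)
  if (sol$status != "optimal") stop("cannot pin optimum: FBA ", sol$status)
  mu <- sol$objective_value
  pinned <- set_bounds(model, objective_id, lb = fraction * mu, ub = mu)
  chk <- solve_fba(pinned, objective_id)
  if (chk$status != "optimal") {
    # numerically pinched: relax the window marginally before giving up
    pinned <- set_bounds(model, objective_id,
                         lb = fraction * mu - 1e-9, ub = mu + 1e-9)
    chk <- solve_fba(pinned, objective_id)
    if (chk$status != "optimal") stop("model infeasible after pinning optimum")
  }
  pinned
}
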