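#' Polymer specification
#'
#' Describes a storage or exopolymer as a mixture of precursor metabolites:
#' mole fractions over precursors (summing to 1), the (mass-weighted) monomer
#' molar mass, and the polymer's dry-weight fraction `f` of total biomass.
#' PHB defaults to `f = 0.50` (half the cell dry mass under nitrogen
#' limitation); EPS variants default to `f = 0.30`.
#'
#' @param id polymer id, e.g. `"PHB"` or `"EPS1"`.
#' @param precursors named numeric vector of mole fractions over
#'   precursor metabolite ids; must sum to 1.
#' @param monomer_mass monomer molar mass in g/mol (mass-weighted average for
#'   mixtures).
#' @param dry_weight_fraction `f` in (0, 1).
#' @return a `polymer_spec`.
#' @export
polymer_spec <- function(id, precursors, monomer_mass, dry_weight_fraction) {
  stopifnot(length(precursors) >= 1, !is.null(names(precursors)))
  if (abs(sum(precursors) - 1) > 1e-9) {
    stop("precursor fractions must sum to 1 (got ", sum(precursors), ")")
  }
  if (dry_weight_fraction <= 0 || dry_weight_fraction >= 1) {
    stop("dry_weight_fraction must lie in (0, 1)")
  }
  stopifnot(monomer_mass > 0)
  structure(list(id = id, precursors = precursors, monomer_mass = monomer_mass,
                 dry_weight_fraction = dry_weight_fraction),
            class = "polymer_spec")
}

#' Default PHB spec for the toy network
#'
#' One precursor (the PHB monomer 3-hydroxybutyrate unit, C4H6O2,
#' 86.09 g/mol) at dry-weight fraction 0.50.
#' @return a [polymer_spec()].
#' @export
phb_spec <- function() {
  polymer_spec("PHB", c(phb_c = 1), monomer_mass = 86.09,
               dry_weight_fraction = 0.50)
}

#' Default EPS specs for the toy network
#'
#' Six EPS variants over the four nucleotide-sugar precursors
#' (UDP-N-acetylglucosamine, UDP-D-galactose, dTDP-L-rhamnose,
#' dTDP-N-acetylfucosamine analogs). The precursor fractions are
#' configurable placeholders — real compositions are experimental inputs —
#' and the monomer masses are fraction-weighted means of the toy precursor
#' masses. Dry-weight fraction 0.30.
#'
#' @return named list of six [polymer_spec()]s (`EPS1` .. `EPS6`).
#' @export
eps_specs <- function() {
  prs <- c("uacgam_c", "udpgal_c", "dtdprmn_c", "dtdpfucac_c")
  masses <- c(uacgam_c = 167.16, udpgal_c = 124.09,
              dtdprmn_c = 106.08, dtdpfucac_c = 149.15)
  fracs <- list(
    EPS1 = c(0.40, 0.30, 0.20, 0.10),
    EPS2 = c(0.10, 0.40, 0.30, 0.20),
    EPS3 = c(0.25, 0.25, 0.25, 0.25),
    EPS4 = c(0.55, 0.15, 0.15, 0.15),
    EPS5 = c(0.15, 0.15, 0.55, 0.15),
    EPS6 = c(0.10, 0.20, 0.30, 0.40))
  out <- lapply(names(fracs), function(nm) {
    fr <- stats::setNames(fracs[[nm]], prs)
    polymer_spec(nm, fr, monomer_mass = sum(fr * masses[prs]),
                 dry_weight_fraction = 0.30)
  })
  stats::setNames(out, names(fracs))
}

#' Add a polymer demand reaction
#'
#' Adds the irreversible pseudo drain
#' `sum_i fraction_i * precursor_i -> (out)` named `DM_<polymer id>`.
#'
#' @param model a `gem_model`.
#' @param spec a [polymer_spec()]; all precursors must exist in the model.
#' @return the model with the demand added.
#' @export
add_polymer_demand <- function(model, spec) {
  stopifnot(inherits(spec, "polymer_spec"))
  missing <- setdiff(names(spec$precursors), metabolite_ids(model))
  if (length(missing)) {
    stop("polymer '", spec$id, "' precursor(s) missing from model: ",
         paste(missing, collapse = ", "))
  }
  id <- paste0("DM_", tolower(spec$id))
  add_reaction(model, id, -spec$precursors, lb = 0, ub = 1000,
               subsystem = "demand", pseudo = TRUE)
}

polymer_demand_id <- function(spec) paste0("DM_", tolower(spec$id))

#' Couple polymer production to biomass composition
#'
#' Enforces the fixed-composition mass balance: a polymer making up fraction
#' `f` of cell dry weight and a biomass reaction producing the remaining
#' `1 - f` satisfy
#' `v_polymer * M / 1000 = (f / (1 - f)) * mu`
#' with `M` the monomer molar mass (g/mmol after the /1000), `v` in
#' mmol/gDW/h and `mu` in 1/h. The relation is added as an equality row of
#' the constraint system (an exact composition, not a ceiling). Optionally
#' also pins `mu`.
#'
#' @param model a `gem_model` already carrying the polymer demand.
#' @param spec the [polymer_spec()].
#' @param mu_target optional growth rate to pin (1/h).
#' @return the constrained model.
#' @export
couple_polymer_to_biomass <- function(model, spec, mu_target = NULL) {
  dem <- polymer_demand_id(spec)
  if (!dem %in% reaction_ids(model)) {
    stop("polymer demand '", dem, "' not in model; call add_polymer_demand() first")
  }
  f <- spec$dry_weight_fraction
  coef <- stats::setNames(c(spec$monomer_mass / 1000, -f / (1 - f)),
                          c(dem, model$objective))
  model$couplings[[paste0("coupling_", tolower(spec$id))]] <-
    list(coef = coef, rhs = 0)
  if (!is.null(mu_target)) {
    model <- set_bounds(model, model$objective, lb = mu_target, ub = mu_target)
  }
  model
}

#' Carbon-to-nitrogen uptake ratio of a solution
#'
#' C is the carbon uptake summed over carbon sources (uptake flux times C
#' atoms per molecule); N sums the nitrogen atoms of the inorganic N source
#' (ammonium when aerobic, nitrate when denitrifying) plus any N in the
#' carbon sources themselves (amino acids, nucleosides, ...). Zero N uptake
#' reports `Inf`.
#'
#' @param solution an optimal `gemflux_fba` solution.
#' @param condition the [growth_condition()] the solution was computed under.
#' @param model the `gem_model` (supplies formulas).
#' @return the molar C:N ratio (dimensionless).
#' @export
compute_cn_ratio <- function(solution, condition, model) {
  stopifnot(solution$status == "optimal")
  flux <- solution$fluxes
  uptake_of <- function(base) {
    ex <- paste0("EX_", base, "_e")
    if (!ex %in% names(flux)) return(0)
    max(0, -flux[[ex]])
  }
  formula_of <- function(base) {
    ide <- paste0(base, "_e")
    model$metabolites$formula[match(ide, model$metabolites$id)]
  }
  c_total <- 0; n_total <- 0
  for (base in names(condition$carbon)) {
    u <- uptake_of(base)
    c_total <- c_total + u * count_element(formula_of(base), "C")
    n_total <- n_total + u * count_element(formula_of(base), "N")
  }
  n_base <- if (condition$aerobic) "nh4" else "no3"
  n_total <- n_total + uptake_of(n_base) * count_element(formula_of(n_base), "N")
  if (n_total <= 0) return(Inf)
  c_total / n_total
}

#' Carbon-to-nitrogen ratio sweep
#'
#' Fixes the molar C:N uptake ratio (nitrogen source at 1 mmol/gDW/h of N,
#' carbon source scaled to the ratio), maximizes growth, then pins the
#' optimal growth rate and maximizes the polymer demand — storage polymer
#' from the carbon left over once growth has claimed its share. Below the
#' stoichiometric C:N ratio of biomass the leftover is zero and no polymer
#' is produced; above it, polymer production rises with the ratio.
#'
#' @param model a `gem_model` with the polymer demand added.
#' @param spec the [polymer_spec()] being produced.
#' @param c_source,n_source base ids of the carbon and nitrogen source
#'   (default acetate / ammonium).
#' @param ratios integer C:N ratios to evaluate (default 1:20).
#' @param aerobic oxygen regime.
#' @return data.frame `ratio`, `feasible`, `mu`, `v_polymer`.
#' @export
cn_sweep <- function(model, spec, c_source = "ac", n_source = "nh4",
                     ratios = 1:20, aerobic = TRUE) {
  dem <- polymer_demand_id(spec)
  if (!dem %in% reaction_ids(model)) {
    stop("polymer demand '", dem, "' not in model")
  }
  cf <- model$metabolites$formula[match(paste0(c_source, "_e"), model$metabolites$id)]
  nC <- count_element(cf, "C")
  if (nC == 0) stop("carbon source '", c_source, "' has no carbon")
  rows <- lapply(ratios, function(r) {
    # medium supplies r mol C per mol N: carbon uptake pinned to r/nC,
    # nitrogen capped at 1 (excess N simply stays unconsumed, as in the
    # nitrogen-limitation experiments the sweep emulates)
    cond <- growth_condition(
      paste0("cn_", r),
      carbon = stats::setNames(0, c_source),
      nitrogen = stats::setNames(1, n_source),
      aerobic = aerobic, minerals = c("pi", "h2o"),
      fixed_uptakes = stats::setNames(r / nC, c_source))
    m <- apply_condition(model, cond)
    sol <- solve_fba(m)
    if (sol$status != "optimal") {
      return(data.frame(ratio = r, feasible = FALSE, mu = NA_real_,
                        v_polymer = NA_real_))
    }
    pinned <- set_bounds(m, model$objective, lb = sol$objective_value,
                         ub = sol$objective_value)
    psol <- solve_fba(pinned, objective_id = dem)
    if (psol$status != "optimal") {
      # pinning at the exact optimum can pinch numerically; back off a hair
      pinned <- set_bounds(m, model$objective,
                           lb = sol$objective_value * (1 - 1e-9),
                           ub = sol$objective_value)
      psol <- solve_fba(pinned, objective_id = dem)
    }
    data.frame(ratio = r, feasible = TRUE, mu = sol$objective_value,
               v_polymer = if (psol$status == "optimal") psol$objective_value else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Yield panel over substrates, polymers and oxygen regimes
#'
#' For every combination of carbon substrate, polymer and oxygen regime:
#' apply the condition (substrate uptake capped at `uptake`), add the mass
#' coupling of the polymer to biomass, maximize the polymer demand, and
#' record the production flux, the yield per carbon atom taken up
#' (`v_polymer / (uptake * nC)`) and the C:N uptake ratio. Substrates the
#' model cannot grow on under the coupling yield a flagged zero record
#' instead of an error.
#'
#' @param model a `gem_model` (demands are added internally as needed).
#' @param substrates character vector of carbon-source base ids.
#' @param polymers list of [polymer_spec()]s.
#' @param regimes subset of `c("aerobic", "anaerobic")`.
#' @param uptake substrate uptake cap in mmol/gDW/h.
#' @return data.frame of yield records: `substrate`, `n_carbons`, `polymer`,
#'   `regime`, `mu`, `production`, `yield_per_c`, `cn_ratio`, `flagged`.
#' @export
yield_panel <- function(model, substrates, polymers,
                        regimes = c("aerobic", "anaerobic"), uptake = 10) {
  rows <- list()
  for (spec in polymers) {
    dem <- polymer_demand_id(spec)
    m0 <- if (dem %in% reaction_ids(model)) model else add_polymer_demand(model, spec)
    mc <- couple_polymer_to_biomass(m0, spec)
    for (substrate in substrates) {
      ex <- paste0("EX_", substrate, "_e")
      nC <- count_element(
        model$metabolites$formula[match(paste0(substrate, "_e"),
                                        model$metabolites$id)] %|0|% NA_character_, "C")
      if (!ex %in% reaction_ids(model)) {
        for (regime in regimes) {
          rows[[length(rows) + 1]] <- data.frame(
            substrate = substrate, n_carbons = NA_integer_, polymer = spec$id,
            regime = regime, mu = 0, production = 0, yield_per_c = 0,
            cn_ratio = NA_real_, flagged = TRUE)
        }
        next
      }
      for (regime in regimes) {
        cond <- condition_substrate(substrate, uptake = uptake,
                                    aerobic = regime == "aerobic")
        m <- apply_condition(mc, cond)
        sol <- solve_fba(m, objective_id = dem)
        if (sol$status != "optimal" || sol$objective_value <= GROWTH_TOL) {
          rows[[length(rows) + 1]] <- data.frame(
            substrate = substrate, n_carbons = nC, polymer = spec$id,
            regime = regime, mu = 0, production = 0, yield_per_c = 0,
            cn_ratio = NA_real_, flagged = TRUE)
          next
        }
        up <- max(GROWTH_TOL, -sol$fluxes[[ex]])
        rows[[length(rows) + 1]] <- data.frame(
          substrate = substrate, n_carbons = nC, polymer = spec$id,
          regime = regime, mu = sol$fluxes[[model$objective]],
          production = sol$objective_value,
          yield_per_c = sol$objective_value / (up * nC),
          cn_ratio = compute_cn_ratio(sol, cond, model),
          flagged = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA of yield-panel records
#'
#' Pivots the records into a substrates x polymers matrix of the chosen
#' value (`cn_ratio` or `yield_per_c`; flagged records are imputed as 0),
#' then runs column-centered PCA via singular value decomposition.
#'
#' @param records data.frame from [yield_panel()], typically one regime.
#' @param value `"cn_ratio"` or `"yield_per_c"`.
#' @return list with `scores` (substrates x components), `loadings`
#'   (polymers x components), `variance_fraction` (sums to 1).
#' @export
pca_yields <- function(records, value = "cn_ratio") {
  stopifnot(value %in% c("cn_ratio", "yield_per_c"))
  v <- records[[value]]
  v[records$flagged | !is.finite(v)] <- 0
  mat <- tapply(v, list(records$substrate, records$polymer), mean)
  mat[is.na(mat)] <- 0
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 substrates and 2 polymers for PCA")
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = varfrac)
}

#' Read a polymer spec from YAML
#'
#' Keys: `id`, `precursors` (map metabolite id -> mole fraction),
#' `monomer_mass`, `dry_weight_fraction`.
#'
#' @param path YAML file.
#' @return a [polymer_spec()].
#' @export
read_polymer_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  polymer_spec(raw$id,
               vapply(raw$precursors, as.numeric, numeric(1)),
               monomer_mass = as.numeric(raw$monomer_mass),
               dry_weight_fraction = as.numeric(raw$dry_weight_fraction))
}
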