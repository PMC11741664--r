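#' Seeded toy genome-scale model of a denitrifying polymer producer
#'
#' Builds a small (~60 reaction) mass- and charge-balanced model of a
#' Gram-negative-like heterotroph with the signature pathways of a
#' denitrifying, polymer-producing wastewater bacterium:
#'
#' * acetate / ammonium / oxygen / nitrate exchanges plus pyruvate, benzoate,
#'   L-alanine, L-serine and formate as alternative carbon sources;
#' * a lumped TCA-like oxidation of acetyl-CoA generating NADH, with aerobic
#'   respiration (NADH + O2 -> ATP) and a denitrification chain
#'   NO3 -> NO2 -> NO -> N2O -> N2 coupled to ATP, partial denitrification
#'   exits (nitrite and nitrous-oxide export) and DNRA (NO2 -> NH4);
#' * aerobic aromatic degradation via catechol meta-cleavage (oxygen-requiring)
#'   and anaerobic degradation via benzoyl-CoA to three acetyl-CoA;
#' * a PHB branch (2 acetyl-CoA -> acetoacetyl-CoA -> 3-hydroxybutyryl-CoA ->
#'   PHB monomer) and four EPS precursor syntheses;
#' * a nitrogen-consuming biomass reaction.
#'
#' Cofactor moieties (CoA, NAD, adenosine) are encoded as placeholder element
#' symbols (`R`, `Q`, `A`) so every non-pseudo reaction is exactly elementally
#' balanced; carbon and nitrogen species carry real formulas so C:N
#' arithmetic is exact. The returned model carries a machine-readable truth
#' sheet (see [model_truth()]) with the analytic growth and yield bounds of
#' the planted stoichiometry.
#'
#' @param include_denitrification,include_dnra,include_aromatic_aerobic,include_aromatic_anaerobic,include_phb,include_eps
#'   toggles for the optional branches.
#' @param biomass_n_per_c mol N consumed by biomass per mol C (default 2/7,
#'   i.e. 3.5 C per N); together with the integer C:N sweep this puts the
#'   PHB onset at the 4:1 ratio.
#' @param seed integer; the builder is deterministic, the seed is recorded in
#'   the truth sheet for provenance.
#' @return a `gem_model` with attribute `"truth"`.
#' @export
make_toy_model <- function(include_denitrification = TRUE,
                           include_dnra = TRUE,
                           include_aromatic_aerobic = TRUE,
                           include_aromatic_anaerobic = TRUE,
                           include_phb = TRUE,
                           include_eps = TRUE,
                           biomass_n_per_c = 2 / 7,
                           seed = 1L) {
  stopifnot(biomass_n_per_c > 0, biomass_n_per_c < 1)
  biomass_atp <- 2
  # aerobic ATP yield is 4 per acetyl-CoA (4 NADH via the TCA lump, 1 ATP per
  # NADH at the oxygen ETC); solve for the biomass acetyl-CoA coefficient so
  # total C per N hits 1 / biomass_n_per_c
  cpn <- 1 / biomass_n_per_c
  bm_accoa <- (cpn - biomass_atp / 4 * 2) / 2
  if (bm_accoa <= 0) stop("biomass_n_per_c too large for the planted ATP cost")

  m <- gem_model("toy_denitrifier")
  met <- function(m, base, name, formula, compartments) {
    for (cp in compartments) {
      m <- add_metabolite(m, paste0(base, "_", cp), name, formula, 0L, cp)
    }
    m
  }
  m <- met(m, "ac", "acetate", "C2H4O2", c("e", "p", "c"))
  m <- met(m, "nh4", "ammonium", "NH3", c("e", "c"))
  m <- met(m, "o2", "oxygen", "O2", c("e", "c"))
  m <- met(m, "no3", "nitrate", "HNO3", c("e", "c"))
  m <- met(m, "no2", "nitrite", "HNO2", c("e", "c"))
  m <- met(m, "no", "nitric oxide", "NO", "c")
  m <- met(m, "n2o", "nitrous oxide", "N2O", c("e", "c"))
  m <- met(m, "n2", "dinitrogen", "N2", c("e", "c"))
  m <- met(m, "co2", "carbon dioxide", "CO2", c("e", "c"))
  m <- met(m, "h2o", "water", "H2O", c("e", "c"))
  m <- met(m, "pi", "phosphate", "H3PO4", c("e", "c"))
  m <- met(m, "pyr", "pyruvate", "C3H4O3", c("e", "c"))
  m <- met(m, "bz", "benzoate", "C7H6O2", c("e", "c"))
  m <- met(m, "catechol", "catechol", "C6H6O2", "c")
  m <- met(m, "bzcoa", "benzoyl-CoA", "C7H5OR", "c")
  m <- met(m, "ala__L", "L-alanine", "C3H7NO2", c("e", "c"))
  m <- met(m, "ser__L", "L-serine", "C3H7NO3", c("e", "c"))
  m <- met(m, "for", "formate", "CH2O2", c("e", "c"))
  m <- met(m, "atp", "ATP", "AHO11P3", "c")
  m <- met(m, "adp", "ADP", "AO8P2", "c")
  m <- met(m, "nad", "NAD+", "Q", "c")
  m <- met(m, "nadh", "NADH", "QH2", "c")
  m <- met(m, "coa", "coenzyme A", "HR", "c")
  m <- met(m, "accoa", "acetyl-CoA", "C2H3OR", "c")
  m <- met(m, "aacoa", "acetoacetyl-CoA", "C4H5O2R", "c")
  m <- met(m, "3hbcoa", "(R)-3-hydroxybutyryl-CoA", "C4H7O2R", "c")
  m <- met(m, "phb", "PHB monomer (3-hydroxybutyrate unit)", "C4H6O2", "c")
  m <- met(m, "uacgam", "UDP-N-acetylglucosamine (synthetic analog)", "C8H9NO3", "c")
  m <- met(m, "udpgal", "UDP-D-galactose (synthetic analog)", "C6H4O2", "c")
  m <- met(m, "dtdprmn", "dTDP-L-rhamnose (synthetic analog)", "C6H2O", "c")
  m <- met(m, "dtdpfucac", "dTDP-N-acetylfucosamine (synthetic analog)", "C8H7NO2", "c")

  rx <- function(m, id, eq, lb = 0, ub = 1000, gpr = NULL, sub = "") {
    add_reaction(m, id, eq, lb = lb, ub = ub, gpr = gpr, subsystem = sub)
  }
  ex <- function(m, base) {
    add_reaction(m, paste0("EX_", base, "_e"),
                 stats::setNames(-1, paste0(base, "_e")),
                 lb = 0, ub = 1000, subsystem = "exchange", pseudo = TRUE)
  }
  for (b in c("ac", "nh4", "o2", "no3", "no2", "n2o", "n2", "co2", "h2o",
              "pi", "pyr", "bz", "ala__L", "ser__L", "for")) m <- ex(m, b)

  tr <- function(m, id, from, to, gpr = NULL) {
    rx(m, id, stats::setNames(c(-1, 1), c(from, to)), lb = -1000, ub = 1000,
       gpr = gpr, sub = "transport")
  }
  m <- tr(m, "ACtex", "ac_e", "ac_p", "tmz0028")
  m <- tr(m, "ACtpc", "ac_p", "ac_c", "tmz0029")
  m <- tr(m, "NH4t", "nh4_e", "nh4_c", "tmz0030")
  m <- tr(m, "O2t", "o2_e", "o2_c")
  m <- tr(m, "NO3t", "no3_e", "no3_c", "tmz0031")
  m <- tr(m, "NO2t", "no2_e", "no2_c", "tmz0032")
  m <- tr(m, "N2Ot", "n2o_e", "n2o_c")
  m <- tr(m, "N2t", "n2_e", "n2_c")
  m <- tr(m, "CO2t", "co2_e", "co2_c")
  m <- tr(m, "H2Ot", "h2o_e", "h2o_c")
  m <- tr(m, "PIt", "pi_e", "pi_c", "tmz0033")
  m <- tr(m, "PYRt", "pyr_e", "pyr_c", "tmz0035")
  m <- tr(m, "ALAt", "ala__L_e", "ala__L_c", "tmz0036")
  m <- tr(m, "SERt", "ser__L_e", "ser__L_c", "tmz0037")
  m <- tr(m, "FORt", "for_e", "for_c", "tmz0038")

  m <- rx(m, "ACS", c(ac_c = -1, coa_c = -1, accoa_c = 1, h2o_c = 1),
          gpr = "tmz0001", sub = "central carbon metabolism")
  m <- rx(m, "PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1,
                      accoa_c = 1, co2_c = 1, nadh_c = 1),
          gpr = "tmz0002 and tmz0003", sub = "central carbon metabolism")
  m <- rx(m, "TCA", c(accoa_c = -1, h2o_c = -3, nad_c = -4,
                      co2_c = 2, coa_c = 1, nadh_c = 4),
          gpr = "tmz0004", sub = "central carbon metabolism")
  m <- rx(m, "ETC_O2", c(nadh_c = -2, o2_c = -1, adp_c = -2, pi_c = -2,
                         nad_c = 2, atp_c = 2, h2o_c = 4),
          gpr = "tmz0005 and tmz0006", sub = "oxidative phosphorylation")
  if (include_denitrification) {
    m <- rx(m, "NAR", c(no3_c = -2, nadh_c = -2, adp_c = -1, pi_c = -1,
                        no2_c = 2, nad_c = 2, atp_c = 1, h2o_c = 3),
            gpr = "tmz0007", sub = "denitrification")
    m <- rx(m, "NIR", c(no2_c = -2, nadh_c = -1, no_c = 2, nad_c = 1, h2o_c = 2),
            gpr = "tmz0008", sub = "denitrification")
    m <- rx(m, "NOR", c(no_c = -2, nadh_c = -1, n2o_c = 1, nad_c = 1, h2o_c = 1),
            gpr = "tmz0009", sub = "denitrification")
    m <- rx(m, "NOS", c(n2o_c = -1, nadh_c = -1, adp_c = -1, pi_c = -1,
                        n2_c = 1, nad_c = 1, atp_c = 1, h2o_c = 2),
            gpr = "tmz0010", sub = "denitrification")
  }
  if (include_dnra) {
    m <- rx(m, "DNRA", c(no2_c = -1, nadh_c = -3, nh4_c = 1, h2o_c = 2, nad_c = 3),
            gpr = "tmz0011", sub = "nitrogen metabolism")
  }
  if (include_aromatic_aerobic) {
    m <- rx(m, "BZDOX", c(bz_c = -2, o2_c = -3, nadh_c = -2,
                          catechol_c = 2, co2_c = 2, h2o_c = 2, nad_c = 2),
            gpr = "tmz0012 or tmz0013", sub = "aromatic degradation (aerobic)")
    m <- rx(m, "CATDOX", c(catechol_c = -1, o2_c = -2, coa_c = -1,
                           pyr_c = 1, accoa_c = 1, co2_c = 1),
            gpr = "tmz0014", sub = "aromatic degradation (aerobic)")
    m <- tr(m, "BZt", "bz_e", "bz_c", "tmz0034")
  } else if (include_aromatic_anaerobic) {
    m <- tr(m, "BZt", "bz_e", "bz_c", "tmz0034")
  }
  if (include_aromatic_anaerobic) {
    m <- rx(m, "BZCOAL", c(bz_c = -1, coa_c = -1, atp_c = -1,
                           bzcoa_c = 1, adp_c = 1, pi_c = 1),
            gpr = "tmz0015", sub = "aromatic degradation (anaerobic)")
    m <- rx(m, "BCR", c(bzcoa_c = -1, coa_c = -2, h2o_c = -6, nad_c = -3,
                        atp_c = -2,
                        accoa_c = 3, co2_c = 1, nadh_c = 3, adp_c = 2, pi_c = 2),
            gpr = "tmz0016 and tmz0017", sub = "aromatic degradation (anaerobic)")
  }
  m <- rx(m, "ALADH", c(ala__L_c = -1, h2o_c = -1, nad_c = -1,
                        pyr_c = 1, nh4_c = 1, nadh_c = 1),
          gpr = "tmz0018", sub = "amino acid metabolism")
  m <- rx(m, "SERD", c(ser__L_c = -1, pyr_c = 1, nh4_c = 1),
          gpr = "tmz0019", sub = "amino acid metabolism")
  m <- rx(m, "FDH", c(for_c = -1, nad_c = -1, co2_c = 1, nadh_c = 1),
          gpr = "tmz0020", sub = "formate metabolism")
  if (include_phb) {
    m <- rx(m, "ACACT", c(accoa_c = -2, aacoa_c = 1, coa_c = 1),
            gpr = "tmz0021", sub = "PHB biosynthesis")
    m <- rx(m, "AACR", c(aacoa_c = -1, nadh_c = -1, `3hbcoa_c` = 1, nad_c = 1),
            gpr = "tmz0022", sub = "PHB biosynthesis")
    m <- rx(m, "PHAS", c(`3hbcoa_c` = -1, phb_c = 1, coa_c = 1),
            gpr = "tmz0023", sub = "PHB biosynthesis")
    m <- add_reaction(m, "SK_phb_c", c(phb_c = -1), lb = 0, ub = 1000,
                      subsystem = "demand", pseudo = TRUE)
  }
  if (include_eps) {
    m <- rx(m, "EPSP1", c(accoa_c = -4, nh4_c = -1, atp_c = -1,
                          uacgam_c = 1, coa_c = 4, adp_c = 1, pi_c = 1),
            gpr = "tmz0024", sub = "EPS biosynthesis")
    m <- rx(m, "EPSP2", c(accoa_c = -3, atp_c = -1,
                          udpgal_c = 1, coa_c = 3, adp_c = 1, pi_c = 1),
            gpr = "tmz0025", sub = "EPS biosynthesis")
    m <- rx(m, "EPSP3", c(accoa_c = -3, atp_c = -2,
                          dtdprmn_c = 1, coa_c = 3, adp_c = 2, pi_c = 2),
            gpr = "tmz0026", sub = "EPS biosynthesis")
    m <- rx(m, "EPSP4", c(accoa_c = -4, nh4_c = -1, atp_c = -2,
                          dtdpfucac_c = 1, coa_c = 4, adp_c = 2, pi_c = 2),
            gpr = "tmz0027", sub = "EPS biosynthesis")
    for (p in c("uacgam", "udpgal", "dtdprmn", "dtdpfucac")) {
      m <- add_reaction(m, paste0("SK_", p, "_c"),
                        stats::setNames(-1, paste0(p, "_c")),
                        lb = 0, ub = 1000, subsystem = "demand", pseudo = TRUE)
    }
  }
  m <- rx(m, "ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
          sub = "maintenance")
  m <- add_reaction(m, "DM_nadh_diss", c(nadh_c = -1, nad_c = 1),
                    lb = 0, ub = 1000, subsystem = "maintenance", pseudo = TRUE)
  bm <- c(accoa_c = -bm_accoa, nh4_c = -1, atp_c = -biomass_atp,
          h2o_c = -biomass_atp,
          coa_c = bm_accoa, adp_c = biomass_atp, pi_c = biomass_atp)
  m <- add_reaction(m, "BIOMASS", bm, lb = 0, ub = 1000,
                    subsystem = "biomass", pseudo = TRUE)
  m <- set_objective(m, "BIOMASS")
  validate_model(m)

  # analytic truth: acetyl-CoA cost per biomass unit under each regime
  accoa_aer <- bm_accoa + biomass_atp / 4      # 1 ATP per NADH, 4 NADH per accoa
  accoa_ana <- bm_accoa + biomass_atp / 2      # best anaerobic ATP: 0.5 per NADH
  attr(m, "truth") <- list(
    seed = seed,
    biomass_accoa = bm_accoa,
    biomass_atp = biomass_atp,
    cn_threshold = 2 * accoa_aer,              # mol C per mol N at zero PHB
    mu_aerobic_acetate10 = 10 / accoa_aer,     # acetate uptake 10 -> 10 accoa
    mu_anaerobic_acetate10 = 10 / accoa_ana,
    phb_yield_per_c_max = 1 / (2 * (2 + 0.25)),  # 2 accoa + NADH from 1/4 accoa
    phb_stoich_bound = 0.25,                   # 1 monomer per 2 acetyl-CoA (4 C)
    dissipation_ids = c("ATPM", "DM_nadh_diss"),
    # moiety-free products reachable under a rich medium (carrier-bound
    # species like acetyl-CoA cannot be drained: the CoA moiety is conserved)
    sink_testable = c("phb_c", "uacgam_c", "udpgal_c", "dtdprmn_c",
                      "dtdpfucac_c", "pyr_c", "co2_c", "catechol_c", "n2_c"),
    carbon_sources = c("ac", "pyr", "bz", "ala__L", "ser__L"),
    non_growth_sources = "for",
    n_containing_sources = c("ala__L", "ser__L")
  )
  m
}

#' Truth sheet of a generated model
#' @param model a model built by [make_toy_model()].
#' @return the list of analytic values planted by the generator.
#' @export
model_truth <- function(model) attr(model, "truth")

#' Random small network for solver cross-checks
#'
#' Generates a feasible random chain-and-branch network with a handful of
#' reactions and finite bounds, suitable for comparing the LP solver against
#' exhaustive vertex enumeration.
#'
#' @param n_mets number of internal metabolites (2..4).
#' @param n_rxns number of reactions (3..8).
#' @param seed RNG seed.
#' @return a `gem_model` with objective on the last reaction.
#' @export
make_random_network <- function(n_mets = 3, n_rxns = 5, seed = 1L) {
  set.seed(seed)
  m <- gem_model(paste0("random_", seed))
  mets <- paste0("m", seq_len(n_mets), "_c")
  for (id in mets) m <- add_metabolite(m, id, id, NA_character_, 0L, "c")
  # source and drain reactions guarantee feasibility of nonzero flux
  m <- add_reaction(m, "R_src", stats::setNames(1, mets[1]),
                    lb = 0, ub = sample(5:10, 1))
  for (j in seq_len(n_rxns - 2)) {
    from <- sample(n_mets, 1)
    to <- sample(setdiff(seq_len(n_mets), from), 1)
    st <- stats::setNames(c(-1, sample(c(1, 1, 2), 1)), c(mets[from], mets[to]))
    rev <- stats::runif(1) < 0.3
    m <- add_reaction(m, paste0("R_", j), st,
                      lb = if (rev) -sample(3:8, 1) else 0, ub = sample(3:10, 1))
  }
  m <- add_reaction(m, "R_obj", stats::setNames(-1, mets[n_mets]),
                    lb = 0, ub = 1000)
  set_objective(m, "R_obj")
}

#' Homology-hit table with planted ground truth
#'
#' Emulates a protein-homology search between a template model's genes and a
#' target genome. A planted fraction of template genes receive a true hit to
#' their target ortholog; scores are drawn to pass exactly the planted
#' optimal parameter set: each true hit passes the planted thresholds, and a
#' planted share sits in the band between the planted thresholds and the next
#' stricter grid cell of each dimension, so any tightening loses hits. Decoy
#' hits (wrong target gene) fail at least one planted threshold but pass
#' looser cells. Noise flips planted truths: with rate `noise` a true hit is
#' degraded below the planted thresholds (a false negative at the optimum)
#' or a decoy is promoted past them (a false positive).
#'
#' @param template_model template `gem_model` whose GPR genes are queried.
#' @param planted_optimum list with `max_e_value`, `min_query_length`,
#'   `min_identity` (the planted best grid cell).
#' @param fraction_true_hits fraction of template genes with a real ortholog.
#' @param noise rate in `[0, 1]` of corrupted assignments.
#' @param n_decoys_per_gene decoy hits per template gene.
#' @param seed RNG seed; tables are reproducible bit-for-bit per seed.
#' @return list with `hits` (data.frame: template_gene, target_gene, e_value,
#'   alignment_length, identity, bitscore), `gold` (data.frame: reaction_id,
#'   gpr_string — curated truth over the mapped genes), and `mapping`
#'   (named vector template gene -> true target gene).
#' @export
make_hit_table <- function(template_model,
                           planted_optimum = list(max_e_value = 1e-5,
                                                  min_query_length = 100,
                                                  min_identity = 35),
                           fraction_true_hits = 1,
                           noise = 0,
                           n_decoys_per_gene = 2,
                           seed = 1L) {
  set.seed(seed)
  tgenes <- model_genes(template_model)
  if (length(tgenes) == 0) stop("template model has no GPR genes")
  true_set <- sort(sample(tgenes, floor(fraction_true_hits * length(tgenes))))
  mapping <- stats::setNames(paste0("TMZ_", sub("^tmz", "", true_set)), true_set)
  po <- planted_optimum
  rows <- list()
  n_true <- length(true_set)
  # band assignment: a third of true hits hug each threshold from above, so
  # every stricter grid cell drops some of them
  band <- if (n_true > 0) sample(rep_len(1:3, n_true)) else integer(0)
  for (i in seq_along(true_set)) {
    tg <- true_set[i]
    ev <- po$max_e_value * stats::runif(1, 0.05, 0.9)
    len <- round(stats::runif(1, po$min_query_length * 1.4, po$min_query_length * 2))
    idy <- round(stats::runif(1, po$min_identity + 8, min(99, po$min_identity + 30)), 1)
    if (band[i] == 1) ev <- po$max_e_value * stats::runif(1, 0.2, 0.99)
    if (band[i] == 2) len <- po$min_query_length + sample(0:10, 1)
    if (band[i] == 3) idy <- po$min_identity + round(stats::runif(1, 0, 3), 1)
    degraded <- stats::runif(1) < noise
    if (degraded) {
      # push the hit below one planted threshold, chosen at random
      k <- sample(3, 1)
      if (k == 1) ev <- po$max_e_value * stats::runif(1, 10, 1e3)
      if (k == 2) len <- round(po$min_query_length * stats::runif(1, 0.3, 0.9))
      if (k == 3) idy <- round(po$min_identity * stats::runif(1, 0.4, 0.9), 1)
    }
    rows[[length(rows) + 1]] <- data.frame(
      template_gene = tg, target_gene = unname(mapping[tg]),
      e_value = ev, alignment_length = len, identity = idy,
      bitscore = round(200 - 10 * log10(ev + 1e-300) / 3 + stats::runif(1, 0, 20), 1),
      stringsAsFactors = FALSE)
  }
  true_bs <- stats::setNames(rep(0, length(tgenes)), tgenes)
  for (row in rows) true_bs[row$template_gene] <- row$bitscore
  for (tg in tgenes) {
    # two strong decoys per gene: better bitscore than the true hit but
    # failing exactly one planted threshold (identity resp. length), so any
    # loosened grid cell admits a wrong best hit and pays in precision
    for (d in 1:2) {
      promoted <- stats::runif(1) < noise
      ev <- po$max_e_value * stats::runif(1, 0.05, 0.9)
      len <- round(po$min_query_length * stats::runif(1, 1.4, 2))
      idy <- po$min_identity + round(stats::runif(1, 5, 20), 1)
      if (!promoted) {
        if (d == 1) idy <- round(stats::runif(1, po$min_identity * 0.58,
                                              po$min_identity - 0.5), 1)
        else len <- round(stats::runif(1, po$min_query_length * 0.52,
                                       po$min_query_length - 1))
      }
      rows[[length(rows) + 1]] <- data.frame(
        template_gene = tg,
        target_gene = paste0("TMZ_decoy_", sub("^tmz", "", tg), "_", d),
        e_value = ev, alignment_length = len, identity = idy,
        bitscore = round(true_bs[[tg]] + stats::runif(1, 5, 30), 1),
        stringsAsFactors = FALSE)
    }
    # weak decoys: low bitscore, fail the e-value threshold entirely
    for (d in seq_len(max(0, n_decoys_per_gene - 2))) {
      ev <- po$max_e_value * stats::runif(1, 50, 1e4)
      rows[[length(rows) + 1]] <- data.frame(
        template_gene = tg,
        target_gene = paste0("TMZ_decoy_", sub("^tmz", "", tg), "_", d + 2L),
        e_value = ev,
        alignment_length = round(po$min_query_length * stats::runif(1, 1.1, 1.8)),
        identity = po$min_identity + round(stats::runif(1, 2, 10), 1),
        bitscore = round(100 + stats::runif(1, 0, 20), 1),
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  # gold standard: the template GPRs with every gene renamed to its true
  # target ortholog (unmapped genes stay template-labeled and are not gold)
  gold <- do.call(rbind, Filter(Negate(is.null), lapply(template_model$reactions, function(r) {
    if (is.null(r$gpr)) return(NULL)
    genes <- gpr_genes(r$gpr)
    if (!all(genes %in% names(mapping))) return(NULL)
    data.frame(reaction_id = r$id,
               gpr_string = gpr_deparse(gpr_substitute(r$gpr, mapping)),
               stringsAsFactors = FALSE)
  })))
  rownames(gold) <- NULL
  list(hits = hits, gold = gold, mapping = mapping)
}

#' Biolog-style phenotype panel with planted truth
#'
#' Generates `n_conditions` aerobic growth conditions over the toy model's
#' substrates with experimental growth calls and high/medium/low classes.
#' A planted fraction of conditions are false negatives by construction:
#' their substrate is formate, which the network oxidizes for redox but
#' cannot assimilate into biomass, while the planted experimental call is
#' growth. Growth classes are tertiles of the planted growth rates.
#'
#' @param model toy model from [make_toy_model()].
#' @param n_conditions panel size.
#' @param planted_fn_rate fraction of false-negative conditions.
#' @param seed RNG seed.
#' @return list with `conditions` (list of [growth_condition()]),
#'   `experimental` (data.frame: condition_id, substrate_id, growth, class)
#'   and `expected` (planted confusion counts).
#' @export
make_phenotype_panel <- function(model, n_conditions = 40,
                                 planted_fn_rate = 0.1, seed = 1L) {
  set.seed(seed)
  truth <- model_truth(model)
  growable <- truth$carbon_sources
  n_fn <- round(planted_fn_rate * n_conditions)
  n_grow <- n_conditions - n_fn
  subs <- sample(growable, n_grow, replace = TRUE)
  uptakes <- round(stats::runif(n_grow, 2, 12), 1)
  conditions <- list(); experimental <- list()
  for (i in seq_len(n_grow)) {
    cid <- sprintf("cond%02d_%s", i, subs[i])
    conditions[[cid]] <- growth_condition(
      cid, carbon = stats::setNames(uptakes[i], subs[i]), nitrogen = c(nh4 = Inf),
      aerobic = TRUE, minerals = c("pi", "h2o"))
    experimental[[cid]] <- data.frame(condition_id = cid, substrate_id = subs[i],
                                      growth = 1L, class = NA_character_,
                                      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_fn)) {
    cid <- sprintf("fncond%02d_for", i)
    conditions[[cid]] <- growth_condition(
      cid, carbon = c(`for` = 10), nitrogen = c(nh4 = Inf),
      aerobic = TRUE, minerals = c("pi", "h2o"))
    experimental[[cid]] <- data.frame(condition_id = cid, substrate_id = "for",
                                      growth = 1L, class = NA_character_,
                                      stringsAsFactors = FALSE)
  }
  experimental <- do.call(rbind, experimental)
  rownames(experimental) <- NULL
  # planted classes: tertiles of the analytic growth rate (uptake-proportional)
  mu_planted <- numeric(n_grow)
  for (i in seq_len(n_grow)) {
    cond <- conditions[[i]]
    sol <- solve_fba(apply_condition(model, cond))
    mu_planted[i] <- sol$objective_value
  }
  cls <- cut(rank(mu_planted, ties.method = "first"),
             breaks = stats::quantile(seq_len(n_grow), c(0, 1/3, 2/3, 1)),
             labels = c("low", "medium", "high"), include.lowest = TRUE)
  experimental$class[seq_len(n_grow)] <- as.character(cls)
  list(conditions = conditions, experimental = experimental,
       expected = list(TP = n_grow, FN = n_fn, FP = 0L, TN = 0L,
                       sensitivity = n_grow / (n_grow + n_fn)))
}
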