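test_that("polymer specs validate fractions and bounds", {
  expect_error(polymer_spec("bad", c(a_c = 0.5, b_c = 0.6), 100, 0.5), "sum to 1")
  expect_error(polymer_spec("bad", c(a_c = 1), 100, 1.2), "dry_weight_fraction")
  spec <- polymer_spec("EPSx", c(a_c = 0.4, b_c = 0.3, c_c = 0.2, d_c = 0.1),
                       120, 0.3)
  expect_equal(sum(spec$precursors), 1)
})

test_that("polymer demands are built from the spec and reject missing precursors", {
  m <- make_toy_model()
  mp <- add_polymer_demand(m, phb_spec())
  expect_true("DM_phb" %in% reaction_ids(mp))
  expect_equal(mp$reactions[["DM_phb"]]$stoich, c(phb_c = -1))
  eps <- eps_specs()$EPS1
  me <- add_polymer_demand(m, eps)
  expect_equal(me$reactions[["DM_eps1"]]$stoich, -eps$precursors)
  ghost <- polymer_spec("ghost", c(nothere_c = 1), 100, 0.5)
  expect_error(add_polymer_demand(m, ghost), "nothere_c")
})

test_that("biomass coupling enforces the stated mass relation", {
  m <- add_polymer_demand(make_toy_model(), phb_spec())
  # f = 0.5, M = 86.09, mu = 0.1 -> v = 0.1 * (0.5/0.5) * 1000 / 86.09
  mc <- couple_polymer_to_biomass(m, phb_spec(), mu_target = 0.1)
  sol <- solve_fba(apply_condition(mc, condition_acetate_aerobic()),
                   objective_id = "DM_phb")
  expect_equal(sol$objective_value, 0.1 * 1000 / 86.09, tolerance = 1e-6)
  # free mu: at any feasible optimum, polymer mass / biomass mass = f/(1-f)
  for (spec in list(phb_spec(),
                    polymer_spec("PHB30", c(phb_c = 1), 86.09, 0.3))) {
    m2 <- add_polymer_demand(make_toy_model(), spec)
    mc2 <- apply_condition(couple_polymer_to_biomass(m2, spec),
                           condition_acetate_aerobic())
    s2 <- solve_fba(mc2, objective_id = paste0("DM_", tolower(spec$id)))
    f <- spec$dry_weight_fraction
    got <- s2$fluxes[[paste0("DM_", tolower(spec$id))]] * spec$monomer_mass / 1000 /
      s2$fluxes[["BIOMASS"]]
    expect_equal(got, f / (1 - f), tolerance = 1e-6, info = spec$id)
  }
})

test_that("C:N ratios follow the uptake formulas", {
  m <- make_toy_model()
  # acetate 10 (2 C each) with ammonium: C = 20, N = mu (biomass demand)
  cond <- condition_acetate_aerobic()
  sol <- solve_fba(apply_condition(m, cond))
  cn <- compute_cn_ratio(sol, cond, m)
  nh4_up <- -sol$fluxes[["EX_nh4_e"]]
  expect_equal(cn, 20 / nh4_up, tolerance = 1e-6)
  # alanine carries its own N (C3 N1): C/N = 3 when no ammonium is drawn
  cond_a <- condition_substrate("ala__L", 10, TRUE)
  sol_a <- solve_fba(apply_condition(m, cond_a))
  cn_a <- compute_cn_ratio(sol_a, cond_a, m)
  up_a <- -sol_a$fluxes[["EX_ala__L_e"]]
  up_n <- max(0, -sol_a$fluxes[["EX_nh4_e"]])
  expect_equal(cn_a, 3 * up_a / (up_a + up_n), tolerance = 1e-6)
  # zero N uptake reports Inf
  dummy <- list(status = "optimal",
                fluxes = c(EX_ac_e = -10, EX_nh4_e = 0, BIOMASS = 0))
  expect_equal(compute_cn_ratio(dummy, cond, m), Inf)
})

test_that("the C:N sweep turns PHB on at the planted threshold, monotonically", {
  m <- add_polymer_demand(make_toy_model(), phb_spec())
  sw <- cn_sweep(m, phb_spec())
  expect_equal(nrow(sw), 20)
  expect_true(all(sw$feasible))
  thr <- ceiling(model_truth(make_toy_model())$cn_threshold)  # 3.5 -> 4
  expect_true(all(sw$v_polymer[sw$ratio < thr] <= 1e-6))
  expect_true(all(sw$v_polymer[sw$ratio >= thr] > 1e-6))
  expect_true(all(diff(sw$v_polymer) >= -1e-9))
  # below the threshold growth is carbon-limited and climbs with the ratio
  expect_true(all(diff(sw$mu) >= -1e-9))
})

test_that("yield panel covers substrates x polymers x regimes with sane records", {
  m <- make_toy_model()
  specs <- list(phb_spec(), eps_specs()$EPS1)
  subs <- c("ac", "pyr", "bz", "ala__L", "ser__L", "for")
  yp <- yield_panel(m, subs, specs)
  expect_equal(nrow(yp), 6 * 2 * 2)
  expect_true(all(yp$yield_per_c >= 0))
  # formate cannot support biomass: flagged zero records, no crash
  expect_true(all(yp$flagged[yp$substrate == "for"]))
  # an unknown substrate is flagged, not fatal
  yp2 <- yield_panel(m, "unobtainium", list(phb_spec()))
  expect_true(all(yp2$flagged))
  # the oxygen-requiring catechol route makes aerobic benzoate at least as
  # productive as anaerobic
  bz <- yp[yp$substrate == "bz" & yp$polymer == "PHB", ]
  expect_gte(bz$yield_per_c[bz$regime == "aerobic"],
             bz$yield_per_c[bz$regime == "anaerobic"] - 1e-9)
  # PHB yield per acetate carbon never beats the pathway stoichiometry bound
  acp <- yp[yp$substrate == "ac" & yp$polymer == "PHB", ]
  expect_true(all(acp$yield_per_c <= model_truth(m)$phb_stoich_bound + 1e-9))
})

test_that("yield per C is invariant under uniform flux rescaling", {
  m <- make_toy_model()
  y1 <- yield_panel(m, "ac", list(phb_spec()), regimes = "aerobic", uptake = 5)
  y2 <- yield_panel(m, "ac", list(phb_spec()), regimes = "aerobic", uptake = 10)
  expect_equal(y1$yield_per_c, y2$yield_per_c, tolerance = 1e-6)
})

test_that("PCA yields sane variance fractions and separates N groups by PC1 sign", {
  m <- make_toy_model()
  specs <- c(list(phb_spec()), unname(eps_specs()))
  subs <- c("ac", "pyr", "bz", "ala__L", "ser__L")
  yp <- yield_panel(m, subs, specs, regimes = "aerobic")
  pc <- pca_yields(yp, value = "cn_ratio")
  expect_equal(sum(pc$variance_fraction), 1, tolerance = 1e-9)
  truth <- model_truth(m)
  n_subs <- truth$n_containing_sources
  free_subs <- setdiff(subs, n_subs)
  s1 <- pc$scores[, 1]
  expect_true(all(sign(s1[n_subs]) == sign(s1[n_subs][1])))
  expect_true(all(sign(s1[free_subs]) == sign(s1[free_subs][1])))
  expect_true(sign(s1[n_subs][1]) != sign(s1[free_subs][1]))
  # rank-1 matrix: PC1 explains everything
  rec <- data.frame(substrate = rep(c("s1", "s2", "s3"), 2),
                    polymer = rep(c("P1", "P2"), each = 3),
                    cn_ratio = c(1, 2, 3, 2, 4, 6), flagged = FALSE)
  pc1 <- pca_yields(rec, value = "cn_ratio")
  expect_equal(pc1$variance_fraction[1], 1, tolerance = 1e-9)
  expect_error(pca_yields(rec[rec$substrate == "s1", ]), "at least 2")
})
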