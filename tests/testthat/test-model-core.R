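two_met_model <- function(fa = "CH4O", fb = "CH4O", ca = 0L, cb = 0L,
                          coef_b = 1) {
  m <- gem_model("mini")
  m <- add_metabolite(m, "a_c", "A", fa, ca, "c")
  m <- add_metabolite(m, "b_c", "B", fb, cb, "c")
  add_reaction(m, "R1", c(a_c = -1, b_c = coef_b), lb = 0, ub = 10)
}

test_that("stoichiometric matrix matches hand-assembled coefficients", {
  m <- two_met_model()
  S <- build_stoichiometric_matrix(m)
  expect_equal(as.numeric(S[, "R1"]), c(-1, 1))
  m2 <- add_reaction(m, "EX_a_c_x", c(a_c = -1), lb = 0, ub = 10, pseudo = TRUE)
  # hand-assembled 2x2
  S2 <- build_stoichiometric_matrix(m2)
  expect_equal(unname(as.matrix(S2)), matrix(c(-1, 1, -1, 0), 2, 2))
  # toy fixture: verify a column against the reaction definition
  toy <- make_toy_model()
  St <- build_stoichiometric_matrix(toy)
  st <- toy$reactions[["TCA"]]$stoich
  expect_equal(as.numeric(St[names(st), "TCA"]), unname(st))
  expect_equal(sum(St[, "TCA"] != 0), length(st))
})

test_that("mass/charge balance flags exactly the planted imbalances", {
  expect_true(all(check_mass_charge_balance(two_met_model())$balanced))
  # A -> 2B loses C1 H4 O1
  bal <- check_mass_charge_balance(two_met_model(coef_b = 2))
  expect_false(bal$balanced)
  imb <- reaction_imbalance(two_met_model(coef_b = 2), "R1")
  expect_equal(imb[["C"]], 1)
  expect_equal(imb[["H"]], 4)
  expect_equal(imb[["O"]], 1)
  # charge-only imbalance
  bal2 <- check_mass_charge_balance(two_met_model(ca = -1L))
  expect_false(bal2$balanced)
  expect_equal(bal2$charge_imbalance, 1L)
  # missing formula is uncheckable, not an error
  bal3 <- check_mass_charge_balance(two_met_model(fa = NA_character_))
  expect_true(bal3$uncheckable)
  # the whole toy fixture is balanced by construction
  toy_bal <- check_mass_charge_balance(make_toy_model())
  expect_true(all(toy_bal$balanced))
  expect_false(any(toy_bal$uncheckable))
})

test_that("dead-end detection respects bounds-implied directionality", {
  m <- gem_model("de")
  m <- add_metabolite(m, "a_c", "a", NA, 0L, "c")
  m <- add_metabolite(m, "b_c", "b", NA, 0L, "c")
  m <- add_metabolite(m, "c_c", "c", NA, 0L, "c")
  m <- add_reaction(m, "R1", c(a_c = -1, b_c = 1), lb = 0, ub = 10)
  m <- add_reaction(m, "R2", c(a_c = 1, c_c = -1), lb = 0, ub = 10)
  de <- find_dead_ends(m)
  expect_setequal(de$metabolite_id, c("b_c", "c_c"))
  expect_equal(de$category[de$metabolite_id == "b_c"], "single_reaction")
  expect_equal(de$category[de$metabolite_id == "c_c"], "single_reaction")
  # b produced by an irreversible reaction, consumed by none, in 2 reactions
  m2 <- add_reaction(m, "R3", c(a_c = -1, b_c = 1), lb = 0, ub = 10)
  de2 <- find_dead_ends(m2)
  expect_equal(de2$category[de2$metabolite_id == "b_c"], "only_product")
  # a reversible reaction makes its sole metabolite a single_reaction record
  m3 <- gem_model("de3")
  m3 <- add_metabolite(m3, "x_c", "x", NA, 0L, "c")
  m3 <- add_reaction(m3, "R1", c(x_c = 1), lb = -10, ub = 10)
  expect_equal(find_dead_ends(m3)$category, "single_reaction")
  # the connected toy fixture has none
  expect_equal(nrow(find_dead_ends(make_toy_model())), 0)
})

test_that("energy-cycle detector is clean on the fixture and flags a planted futile pair", {
  m <- make_toy_model()
  ec <- detect_energy_cycles(m, model_truth(m)$dissipation_ids)
  expect_true(all(ec <= 1e-6))
  # plant a futile ATP-generating pair: ADP + Pi -> ATP + H2O for free
  bad <- add_reaction(m, "PK1", c(adp_c = -1, pi_c = -1, atp_c = 1, h2o_c = 1),
                      lb = 0, ub = 1000)
  ec2 <- detect_energy_cycles(bad, "ATPM")
  expect_gt(ec2[["ATPM"]], 1e-6)
  # a thermodynamically consistent reversible pair stays clean
  ok <- add_reaction(m, "ACRev", c(ac_c = -1, coa_c = -1, accoa_c = 1, h2o_c = 1),
                     lb = -1000, ub = 1000)
  ec3 <- detect_energy_cycles(ok, model_truth(m)$dissipation_ids)
  expect_true(all(ec3 <= 1e-6))
})

test_that("duplicate unification rewrites ids and collapses copies", {
  m <- gem_model("dup")
  m <- add_metabolite(m, "glc__D_c", "glucose", "C6H12O6", 0L, "c")
  m <- add_metabolite(m, "glucose_c", "glucose legacy", "C6H12O6", 0L, "c")
  m <- add_metabolite(m, "g6p_c", "G6P", "C6H13O9P", 0L, "c")
  m <- add_reaction(m, "HEX1", c(glc__D_c = -1, g6p_c = 1), lb = 0, ub = 10,
                    gpr = "gA")
  m <- add_reaction(m, "HEX1b", c(glucose_c = -1, g6p_c = 1), lb = 0, ub = 5,
                    gpr = "gB")
  expect_warning(u <- unify_duplicate_metabolites(m, c(glucose_c = "glc__D_c")),
                 "bounds")
  expect_equal(length(u$reactions), 1L)
  kept <- u$reactions[[1]]
  expect_equal(kept$ub, 10)                       # widest bounds win
  expect_setequal(gpr_genes(kept$gpr), c("gA", "gB"))
  expect_false("glucose_c" %in% metabolite_ids(u))
  # identity on the empty table; cross-compartment synonyms rejected
  expect_identical(unify_duplicate_metabolites(m, character(0)), m)
  expect_error(unify_duplicate_metabolites(m, c(glucose_c = "glc__D_e")),
               "cross-compartment")
})

test_that("model invariants are enforced at construction", {
  m <- gem_model("inv")
  m <- add_metabolite(m, "a_c", "a", NA, 0L, "c")
  expect_error(add_metabolite(m, "a_c", "again", NA, 0L, "c"), "duplicate")
  expect_error(add_metabolite(m, "b_e", "b", NA, 0L, "c"), "disagrees")
  expect_error(add_reaction(m, "R1", c(zz_c = -1)), "unknown metabolite")
  expect_error(add_reaction(m, "R1", c(a_c = -1), lb = 5, ub = 1), "lb > ub")
  expect_error(add_reaction(m, "EX_a_c", c(a_c = -1), pseudo = FALSE), "pseudo")
  expect_error(add_reaction(m, "R1", c(a_c = -1), pseudo = TRUE), "pseudo")
})
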