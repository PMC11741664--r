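parallel_routes_model <- function() {
  # two routes from substrate to biomass precursor: capacity 10 (gene gBig)
  # and capacity 4 (gene gSmall); uptake 10
  m <- gem_model("parallel")
  m <- add_metabolite(m, "s_e", "S", NA, 0L, "e")
  m <- add_metabolite(m, "s_c", "S", NA, 0L, "c")
  m <- add_metabolite(m, "p_c", "P", NA, 0L, "c")
  m <- add_reaction(m, "EX_s_e", c(s_e = -1), lb = -10, ub = 1000, pseudo = TRUE)
  m <- add_reaction(m, "St", c(s_e = -1, s_c = 1), lb = 0, ub = 1000, gpr = "gUp")
  m <- add_reaction(m, "Rbig", c(s_c = -1, p_c = 1), lb = 0, ub = 10, gpr = "gBig")
  m <- add_reaction(m, "Rsmall", c(s_c = -1, p_c = 1), lb = 0, ub = 4, gpr = "gSmall")
  m <- add_reaction(m, "BIOMASS", c(p_c = -1), lb = 0, ub = 1000, pseudo = TRUE)
  set_objective(m, "BIOMASS")
}

par_condition <- function() {
  growth_condition("par", carbon = c(s = 10), aerobic = TRUE, acceptor = NULL,
                   minerals = character(0))
}

test_that("gene deletions classify sole routes, isozymes and partial routes", {
  m <- parallel_routes_model()
  # the s exchange has no oxygen in this toy; give it a fake acceptor-free condition
  cond <- growth_condition("c1", carbon = c(s = 10), aerobic = TRUE)
  res <- single_gene_deletion(m, list(c1 = cond))
  rec <- res$records
  expect_equal(rec$class[rec$entity == "gUp"], "lethal")       # sole transporter
  expect_equal(rec$ratio[rec$entity == "gBig"], 0.4, tolerance = 1e-9)
  expect_equal(rec$class[rec$entity == "gBig"], "growth_reducing")
  expect_equal(rec$class[rec$entity == "gSmall"], "non_essential")
  expect_true(all(rec$ratio <= 1 + 1e-6))
})

test_that("isozyme pairs survive single deletions on the toy model", {
  m <- make_toy_model()
  conds <- list(bz_aer = condition_substrate("bz", 10, TRUE))
  res <- single_gene_deletion(m, conds, genes = c("tmz0012", "tmz0013", "tmz0014"))
  rec <- res$records
  # either aromatic dioxygenase isozyme alone is dispensable
  expect_equal(rec$class[rec$entity == "tmz0012"], "non_essential")
  expect_equal(rec$class[rec$entity == "tmz0013"], "non_essential")
})

test_that("gene and reaction screens match the exhaustive oracle exactly", {
  m <- make_toy_model()
  conds <- toy_conditions()
  res_g <- single_gene_deletion(m, conds)
  ora_g <- exhaustive_deletion(m, conds, by = "gene")
  merged <- merge(res_g$records, ora_g, by = c("entity", "condition"),
                  suffixes = c("_pkg", "_oracle"))
  expect_equal(nrow(merged), nrow(res_g$records))
  expect_identical(merged$class_pkg, merged$class_oracle)

  res_r <- single_reaction_deletion(m, conds)
  ora_r <- exhaustive_deletion(m, conds, by = "reaction")
  merged_r <- merge(res_r$records, ora_r, by = c("entity", "condition"),
                    suffixes = c("_pkg", "_oracle"))
  expect_equal(nrow(merged_r), nrow(res_r$records))
  expect_identical(merged_r$class_pkg, merged_r$class_oracle)
  # pseudo reactions are excluded; orphans are included and labeled
  expect_false(any(vapply(res_r$records$entity,
                          function(id) m$reactions[[id]]$pseudo, logical(1))))
  expect_true(any(res_r$records$orphan))
})

test_that("deleting the biomass-feeding route is lethal everywhere", {
  m <- make_toy_model()
  conds <- toy_conditions()
  res <- single_reaction_deletion(m, conds)
  # every route to acetyl-CoA severed: TCA feeds NADH for ATP everywhere
  rec <- res$records
  nh4t <- rec[rec$entity == "NH4t", ]
  # ammonium transport is lethal aerobically (no other N source); under
  # nitrate the DNRA route rescues growth at a redox cost
  expect_equal(nh4t$class[nh4t$condition == "ac_aer"], "lethal")
  expect_equal(nh4t$class[nh4t$condition == "ac_ana"], "growth_reducing")
  expect_gt(nh4t$ratio[nh4t$condition == "ac_ana"], 0.5)
})

test_that("global classes follow the all/any aggregation rules and partition", {
  recs <- data.frame(
    entity = rep(c("e1", "e2", "e3", "e4"), each = 2),
    condition = rep(c("c1", "c2"), 4),
    ko_mu = 0, ratio = 0,
    class = c("lethal", "lethal",          # e1: lethal everywhere
              "lethal", "non_essential",   # e2: lethal somewhere
              "growth_reducing", "non_essential",
              "non_essential", "non_essential"),
    stringsAsFactors = FALSE)
  s_all <- summarize_essentiality(recs, lethal_rule = "all")
  expect_equal(s_all$global_class[match(c("e1", "e2", "e3", "e4"), s_all$entity)],
               c("lethal", "growth_reducing", "growth_reducing", "non_essential"))
  s_any <- summarize_essentiality(recs, lethal_rule = "any")
  expect_equal(s_any$global_class[match(c("e1", "e2"), s_any$entity)],
               c("lethal", "lethal"))
  expect_equal(sort(table(s_all$global_class))[["lethal"]], 1)
  expect_equal(nrow(s_all), 4)  # classes partition the entities
})

test_that("lethal-set intersections match inclusion-exclusion", {
  # identical sets: one group containing all
  cmp <- lethal_set_comparison(list(A = c("r1", "r2"), B = c("r1", "r2")))
  expect_equal(nrow(cmp$groups), 1)
  expect_equal(cmp$groups$pattern, "A&B")
  expect_equal(cmp$groups$count, 2)
  # disjoint singletons
  cmp2 <- lethal_set_comparison(list(A = "a", B = "b"))
  expect_setequal(cmp2$groups$pattern, c("A", "B"))
  expect_true(all(cmp2$groups$count == 1))
  # random sets vs direct enumeration oracle
  set.seed(4)
  universe <- sprintf("r%02d", 1:30)
  sets <- lapply(stats::setNames(nm = LETTERS[1:4]),
                 function(i) sample(universe, sample(5:20, 1)))
  cmp3 <- lethal_set_comparison(sets)
  # oracle: classify each entity by its exact membership pattern
  for (ent in unique(unlist(sets))) {
    pat <- paste(names(sets)[vapply(sets, function(s) ent %in% s, logical(1))],
                 collapse = "&")
    row <- cmp3$groups[cmp3$groups$pattern == pat, ]
    expect_true(ent %in% row$members[[1]], info = ent)
  }
  expect_equal(sum(cmp3$groups$count), length(unique(unlist(sets))))
})
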