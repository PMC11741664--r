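po <- list(max_e_value = 1e-5, min_query_length = 100, min_identity = 35)

test_that("hit filtering applies the three thresholds and is monotone", {
  hits <- data.frame(
    template_gene = c("t1", "t2", "t3", "t4"),
    target_gene = c("g1", "g2", "g3", "g4"),
    e_value = c(1e-6, 1e-4, 1e-6, 1e-6),
    alignment_length = c(120, 120, 80, 120),
    identity = c(40, 40, 40, 30),
    bitscore = c(200, 180, 160, 150))
  kept <- filter_hits(hits, po)
  expect_equal(kept$template_gene, "t1")   # t2 fails e-value, t3 length, t4 identity
  expect_equal(nrow(filter_hits(hits[0, ], po)), 0)
  # monotone: loosening any threshold never drops a retained hit
  for (loose in list(list(max_e_value = 1e-3, min_query_length = 100, min_identity = 35),
                     list(max_e_value = 1e-5, min_query_length = 50, min_identity = 35),
                     list(max_e_value = 1e-5, min_query_length = 100, min_identity = 20))) {
    expect_true(all(kept$template_gene %in% filter_hits(hits, loose)$template_gene))
  }
})

test_that("best-hit mapping is deterministic under ties", {
  hits <- data.frame(
    template_gene = c("t1", "t1", "t1"),
    target_gene = c("gB", "gA", "gC"),
    e_value = c(1e-8, 1e-8, 1e-20),
    alignment_length = 120, identity = 40,
    bitscore = c(150, 150, 150))
  bh <- best_hits(hits)
  expect_equal(unname(bh["t1"]), "gC")     # lower e-value wins the tie
  hits$e_value <- 1e-8
  expect_equal(unname(best_hits(hits)["t1"]), "gA")  # then lexicographic
})

test_that("GPR mapping recovers planted orthologs and flags unmapped leaves", {
  m <- make_toy_model()
  tab <- make_hit_table(m, seed = 3)
  draft <- map_gprs(m, filter_hits(tab$hits, po))
  for (id in reaction_ids(draft)) {
    r <- draft$reactions[[id]]
    if (r$pseudo || is.null(r$gpr)) next
    expect_identical(gpr_deparse(r$gpr),
                     gpr_deparse(gpr_substitute(m$reactions[[id]]$gpr, tab$mapping)),
                     info = id)
  }
  expect_length(draft$template_genes, 0)
  # partial mapping leaves template genes flagged
  tab2 <- make_hit_table(m, fraction_true_hits = 0.5, seed = 4)
  d2 <- map_gprs(m, filter_hits(tab2$hits, po))
  unmapped_in_draft <- setdiff(unlist(lapply(d2$reactions, function(r) gpr_genes(r$gpr))),
                               c(tab2$mapping, names(tab2$mapping)))
  expect_setequal(d2$template_genes, intersect(unmapped_in_draft, model_genes(m)))
})

test_that("grid search selects the planted optimum and degrades with noise", {
  m <- make_toy_model()
  tab <- make_hit_table(m, seed = 3)
  gs <- grid_search(tab$hits, m, tab$gold)
  expect_equal(nrow(gs$results), 144)
  expect_equal(gs$optimum$max_e_value, po$max_e_value)
  expect_equal(gs$optimum$min_query_length, po$min_query_length)
  expect_equal(gs$optimum$min_identity, po$min_identity)
  expect_equal(gs$optimum$F1, 1)
  expect_equal(sum(gs$results$F1 == 1), 1)  # uniquely optimal
  expect_error(grid_search(tab$hits, m, tab$gold[0, ]), "empty")
  # precision/recall/F1 internal consistency on every cell
  r <- gs$results
  has <- r$TP + r$FP > 0
  expect_equal(r$precision[has], (r$TP / (r$TP + r$FP))[has])
  expect_equal(r$F1, ifelse(is.na(r$precision) | is.na(r$recall) | r$precision + r$recall == 0, 0,
                            2 * r$precision * r$recall / (r$precision + r$recall)))
})

test_that("degenerate table where all hits pass ties toward the strictest e-value", {
  hits <- data.frame(
    template_gene = c("tmz0001", "tmz0004"),
    target_gene = c("TMZ_0001", "TMZ_0004"),
    e_value = 1e-40, alignment_length = 300, identity = 80,
    bitscore = c(300, 280))
  gold <- data.frame(reaction_id = c("ACS", "TCA"),
                     gpr_string = c("TMZ_0001", "TMZ_0004"))
  gs <- grid_search(hits, make_toy_model(), gold)
  expect_equal(gs$optimum$max_e_value, 1e-30)
  expect_true(all(gs$results$F1 == gs$results$F1[1]))
})

test_that("draft merging keeps the best-supported copy and unions the rest", {
  m <- make_toy_model()
  tab <- make_hit_table(m, seed = 3)
  draft <- map_gprs(m, filter_hits(tab$hits, po))
  # two "templates": same reactions, different provenance scores
  d1 <- draft; d2 <- draft
  d1$id <- "template1"; d2$id <- "template2"
  for (id in reaction_ids(d1)) {
    if (!is.null(d1$reactions[[id]]$provenance)) {
      d1$reactions[[id]]$provenance$bitscore <- 150
      d1$reactions[[id]]$gpr <- gpr_parse("winner")
      d2$reactions[[id]]$provenance$bitscore <- 90
    }
  }
  merged <- merge_drafts(list(d1, d2))
  expect_equal(length(merged$reactions), length(draft$reactions))
  for (id in reaction_ids(merged)) {
    if (!is.null(merged$reactions[[id]]$provenance)) {
      expect_equal(gpr_deparse(merged$reactions[[id]]$gpr), "winner", info = id)
    }
  }
  # disjoint drafts union additively
  half <- reaction_ids(d2)[seq_len(20)]
  dA <- d2; dB <- d2
  for (id in setdiff(reaction_ids(d2), half)) dA <- gemflux:::drop_reaction(dA, id)
  for (id in half) dB <- gemflux:::drop_reaction(dB, id)
  mAB <- merge_drafts(list(dA, dB))
  expect_equal(length(mAB$reactions), length(dA$reactions) + length(dB$reactions))
  # order independence given distinct bitscores
  m12 <- merge_drafts(list(d1, d2)); m21 <- merge_drafts(list(d2, d1))
  expect_identical(
    lapply(m12$reactions[sort(names(m12$reactions))], function(r) gpr_deparse(r$gpr)),
    lapply(m21$reactions[sort(names(m21$reactions))], function(r) gpr_deparse(r$gpr)))
  # stoichiometry conflicts are loud
  dc <- d2
  dc$reactions[["ACS"]]$stoich <- c(ac_c = -2, coa_c = -1, accoa_c = 1, h2o_c = 1)
  expect_error(merge_drafts(list(d1, dc)), "conflict")
})

test_that("template-gene stripping prunes isozymes and orphans broken complexes", {
  m <- gem_model("strip")
  m <- add_metabolite(m, "a_c", "a", NA, 0L, "c")
  m <- add_reaction(m, "R1", c(a_c = 1), lb = 0, ub = 10, gpr = "gA or tX")
  m <- add_reaction(m, "R2", c(a_c = -1), lb = 0, ub = 10, gpr = "gA and tX")
  m$template_genes <- "tX"
  st <- strip_template_genes(m)
  expect_equal(gpr_deparse(st$model$reactions[["R1"]]$gpr), "gA")
  expect_null(st$model$reactions[["R2"]]$gpr)
  expect_setequal(st$report$reaction_id, c("R1", "R2"))
  expect_equal(st$report$outcome[st$report$reaction_id == "R2"], "orphaned")
})
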