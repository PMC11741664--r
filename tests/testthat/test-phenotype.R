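test_that("panel prediction reproduces planted confusion counts", {
  m <- make_toy_model()
  pan <- make_phenotype_panel(m, n_conditions = 40, planted_fn_rate = 0.1, seed = 2)
  res <- predict_growth_panel(m, pan$conditions, pan$experimental)
  expect_equal(res$summary$TP, 36L)
  expect_equal(res$summary$FN, 4L)
  expect_equal(res$summary$FP, 0L)
  expect_equal(res$summary$accuracy, 0.9)
  expect_equal(res$summary$sensitivity, 0.9)
  expect_equal(res$summary$ppv, 1.0)
})

test_that("confusion summary equals a hand tally on a random panel", {
  m <- make_toy_model()
  pan <- make_phenotype_panel(m, n_conditions = 20, planted_fn_rate = 0.2, seed = 5)
  # randomize the experimental truth so all four cells can occur
  set.seed(9)
  exp2 <- pan$experimental
  exp2$growth <- rbinom(nrow(exp2), 1, 0.6)
  res <- predict_growth_panel(m, pan$conditions, exp2)
  cc <- res$calls
  expect_equal(res$summary$TP, sum(cc$predicted_growth & cc$experimental_growth))
  expect_equal(res$summary$TN, sum(!cc$predicted_growth & !cc$experimental_growth))
  expect_equal(res$summary$FP, sum(cc$predicted_growth & !cc$experimental_growth))
  expect_equal(res$summary$FN, sum(!cc$predicted_growth & cc$experimental_growth))
  expect_equal(res$summary$accuracy,
               (res$summary$TP + res$summary$TN) / nrow(res$calls))
})

test_that("unmappable substrates are excluded, not fatal", {
  m <- make_toy_model()
  conds <- list(good = condition_acetate_aerobic(),
                bad = growth_condition("bad", carbon = c(unobtainium = 10),
                                       nitrogen = c(nh4 = Inf)))
  expdf <- data.frame(condition_id = c("good", "bad"),
                      substrate_id = c("ac", "unobtainium"),
                      growth = c(1L, 1L), class = NA_character_)
  res <- predict_growth_panel(m, conds, expdf)
  expect_equal(res$excluded, "bad")
  expect_equal(nrow(res$calls), 1L)
})

test_that("growth-level classification maps ranks and preserves marginals", {
  calls <- data.frame(
    condition_id = sprintf("c%02d", 1:9),
    predicted_mu = c(9, 8, 7, 6, 5, 4, 3, 2, 1),
    predicted_growth = TRUE, experimental_growth = TRUE, call = "TP",
    experimental_class = rep(c("high", "medium", "low"), each = 3),
    stringsAsFactors = FALSE)
  out <- classify_growth_levels(calls)
  expect_equal(out$predicted_class, calls$experimental_class)
  expect_true(all(out$class_outcome == "correct"))
  # marginals preserved even when ranks disagree
  perm <- calls
  perm$experimental_class <- c("medium", "high", "high", "low", "medium",
                               "medium", "low", "low", "high")
  out2 <- classify_growth_levels(perm)
  expect_equal(table(out2$predicted_class), table(perm$experimental_class))
  # invariance under strictly monotone transforms of mu
  tr <- perm
  tr$predicted_mu <- exp(perm$predicted_mu / 3)
  out3 <- classify_growth_levels(tr)
  expect_identical(out3$predicted_class, out2$predicted_class)
  expect_identical(out3$class_outcome, out2$class_outcome)
})

test_that("planted rank swaps are recovered as under/over-estimations", {
  n <- 12
  calls <- data.frame(
    condition_id = sprintf("c%02d", seq_len(n)),
    predicted_mu = as.numeric(seq_len(n)),
    predicted_growth = TRUE, experimental_growth = TRUE, call = "TP",
    experimental_class = rep(c("low", "medium", "high"), each = 4),
    stringsAsFactors = FALSE)
  # swap one borderline pair across the low/medium boundary: conditions 4 and 5
  calls$experimental_class[c(4, 5)] <- c("medium", "low")
  out <- classify_growth_levels(calls)
  expect_equal(sum(out$class_outcome != "correct"), 2L)
  expect_equal(out$class_outcome[4], "under")   # predicted low, truth medium
  expect_equal(out$class_outcome[5], "over")    # predicted medium, truth low
})

test_that("classification is skipped gracefully below 3 conditions", {
  calls <- data.frame(condition_id = c("a", "b"), predicted_mu = c(1, 2),
                      predicted_growth = TRUE, experimental_growth = TRUE,
                      call = "TP", experimental_class = c("low", "high"),
                      stringsAsFactors = FALSE)
  expect_message(out <- classify_growth_levels(calls), "skipped")
  expect_true(all(is.na(out$predicted_class)))
})

test_that("subsystem activity sums absolute fluxes, drops dead subsystems, z-scores", {
  m <- make_toy_model()
  sols <- list(
    ac = solve_fba(apply_condition(m, condition_acetate_aerobic())),
    bz = solve_fba(apply_condition(m, condition_substrate("bz", 10, TRUE))))
  sa <- subsystem_activity(m, sols)
  # hand check one cell: denitrification is inactive aerobically on acetate
  expect_false("denitrification" %in% colnames(sa$activity) &&
               sa$activity["ac", "denitrification"] > 1e-6)
  # activity is the sum of |flux| over members
  subs <- vapply(m$reactions, function(r) r$subsystem, character(1))
  member <- names(subs)[subs == "central carbon metabolism"]
  expect_equal(sa$activity["ac", "central carbon metabolism"],
               sum(abs(sols$ac$fluxes[member])))
  # z-scores have mean 0 per retained subsystem; constant columns are all 0
  expect_true(all(abs(colMeans(sa$zscores)) < 1e-9))
  same <- list(ac = sols$ac, ac2 = sols$ac)
  sa2 <- subsystem_activity(m, same)
  expect_true(all(sa2$zscores == 0))
})
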