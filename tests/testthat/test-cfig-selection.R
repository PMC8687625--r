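test_that("worked greedy traces", {
  # one ingredient covering everything
  one <- data.frame(ingredient_id = "A", target_gene = paste0("G", 1:5))
  sel <- icp_select(one, paste0("G", 1:5))
  expect_equal(nrow(sel$picks), 1)
  expect_equal(sel$achieved_coverage, 1)
  expect_equal(coverage_curve(sel)$cumulative_coverage, 1)

  # A {1,2,3}, B {3,4}, C {5}: picks A (.6), B (.8), C (1.0)
  assoc <- data.frame(
    ingredient_id = c("A", "A", "A", "B", "B", "C"),
    target_gene = paste0("G", c(1, 2, 3, 3, 4, 5)))
  sel <- icp_select(assoc, paste0("G", 1:5), coverage_target = 0.9)
  expect_equal(sel$picks$ingredient_id, c("A", "B", "C"))
  expect_equal(sel$picks$cumulative_coverage, c(0.6, 0.8, 1.0))
  expect_equal(coverage_curve(sel)$cumulative_coverage, c(0.6, 0.8, 1.0))

  # a duplicate of the leader is never picked: zero marginal gain
  assoc2 <- data.frame(
    ingredient_id = c("A", "A", "A", "B", "B", "B", "C"),
    target_gene = paste0("G", c(1, 2, 3, 1, 2, 3, 4)))
  sel2 <- icp_select(assoc2, paste0("G", 1:4), coverage_target = 1)
  expect_equal(sel2$picks$ingredient_id, c("A", "C"))
})

test_that("greedy selection matches the from-scratch trace oracle", {
  set.seed(101)
  for (rep in 1:60) {
    sets <- random_icp_instance(sample(2:12, 1), sample(3:20, 1))
    pool <- unique(unlist(sets))
    key <- sample(pool, max(1, round(0.7 * length(pool))))
    want <- oracle_greedy_trace(sets, key)
    sel <- icp_select(sets_to_assoc(sets), key, coverage_target = 1)
    expect_equal(sel$picks$ingredient_id, want$picks)
    expect_equal(sel$picks$marginal_gain, want$gains)
    expect_equal(sel$achieved_coverage, want$coverage)
  }
})

test_that("greedy coverage meets the (1 - 1/e) guarantee vs the optimum", {
  set.seed(55)
  bound <- 1 - exp(-1)
  for (rep in 1:12) {
    sets <- random_icp_instance(sample(4:10, 1), sample(6:16, 1))
    key <- unique(unlist(sets))
    sel <- icp_select(sets_to_assoc(sets), key, coverage_target = 1)
    curve <- coverage_curve(sel)
    for (k in seq_len(min(4, nrow(curve)))) {
      opt <- oracle_best_k_coverage(sets, key, k)
      expect_gte(curve$cumulative_coverage[k] + 1e-12, bound * opt)
    }
  }
})

test_that("picks are unique with strictly positive gains, deterministically", {
  set.seed(77)
  sets <- random_icp_instance(10, 15)
  key <- unique(unlist(sets))
  s1 <- icp_select(sets_to_assoc(sets), key, coverage_target = 1)
  s2 <- icp_select(sets_to_assoc(sets), key, coverage_target = 1)
  expect_identical(s1$picks, s2$picks)
  expect_false(any(duplicated(s1$picks$ingredient_id)))
  expect_true(all(s1$picks$marginal_gain > 0))
  expect_true(all(diff(s1$picks$cumulative_coverage) > 0))
})

test_that("ties break by raw target count then lexicographic id", {
  # B and Z gain 2 key proteins each; Z has more raw targets and wins
  assoc <- data.frame(
    ingredient_id = c("B", "B", "Z", "Z", "Z"),
    target_gene = c("G1", "G2", "G3", "G4", "X1"))
  sel <- icp_select(assoc, paste0("G", 1:4), coverage_target = 1)
  expect_equal(sel$picks$ingredient_id, c("Z", "B"))
  # equal raw counts: lexicographic id
  assoc2 <- data.frame(ingredient_id = c("B", "A"), target_gene = c("G1", "G2"))
  sel2 <- icp_select(assoc2, c("G1", "G2"), coverage_target = 1)
  expect_equal(sel2$picks$ingredient_id, c("A", "B"))
})

test_that("an unreachable coverage target is flagged, not fudged", {
  assoc <- data.frame(ingredient_id = "A", target_gene = "G1")
  sel <- icp_select(assoc, paste0("G", 1:4), coverage_target = 0.9)
  expect_true(sel$unreachable)
  expect_equal(sel$achieved_coverage, 0.25)
  expect_error(icp_select(assoc, character(0)), "empty",
               class = "cfig_validation_error")
  expect_error(icp_select(assoc, "G1", coverage_target = 0), "coverage_target",
               class = "cfig_validation_error")
})

test_that("recovery score counts planted ingredients in the leading picks", {
  assoc <- data.frame(
    ingredient_id = rep(c("P1", "P2", "X1"), each = 2),
    target_gene = paste0("G", c(1, 2, 3, 4, 5, 6)))
  sel <- icp_select(assoc, paste0("G", 1:6), coverage_target = 1)
  expect_equal(recovery_score(sel, c("P1", "P2")), 1)
  expect_equal(recovery_score(sel, c("Q1", "Q2")), 0)
  expect_error(recovery_score(sel, character(0)), "empty",
               class = "cfig_validation_error")
})

test_that("planted critical ingredients lead the selection on a study", {
  b <- planted_recovery_benchmark(study_config(), seeds = 7)
  expect_gte(b$recovery, 0.8)
})
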