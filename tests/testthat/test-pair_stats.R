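# Co-localization resampling and the co-function expectation.

test_that("saturated co-localization gives zero excess every iteration", {
  branch <- setNames(c(rep("br3", 3), rep("br0", 4)), paste0("p", 1:7))
  comp <- setNames(rep("Nucleus", 7), paste0("p", 1:7))
  res <- colocalization_excess(branch, comp, "A", n_iter = 20, seed = 1)
  r3 <- res[res$branch == "br3", ]
  expect_equal(r3$co_intra, 3)
  expect_equal(r3$mean_excess, 0)
  expect_equal(r3$sd_excess, 0)
})

test_that("mean excess matches exhaustive enumeration on a toy pool", {
  # target: 3 proteins, all Nucleus (co_intra = 3, intra_num = 3)
  # comparison pool (strategy A): 3 x 3 pairs of which exactly 3 are
  # co-localized; sampled co-counts are hypergeometric(9, 3, 3)
  branch <- setNames(c(rep("br4", 3), rep("br0", 3)), paste0("p", 1:6))
  comp <- setNames(c(rep("Nucleus", 3), "Nucleus", "Cytoplasm",
                     "Extracellular"), paste0("p", 1:6))
  # enumeration oracle: E[excess | co_s > 0]
  pk <- dhyper(0:3, 3, 6, 3)
  vals <- 100 * (3 - (1:3)) / (1:3)
  expected_mean <- sum(pk[2:4] * vals) / sum(pk[2:4])
  res <- colocalization_excess(branch, comp, "A", n_iter = 4000, seed = 11)
  r <- res[res$branch == "br4", ]
  se <- r$sd_excess / sqrt(r$n_iter_used)
  expect_lt(abs(r$mean_excess - expected_mean), 4 * se)
  # zero-denominator iterations (co_s = 0) are excluded, not smoothed
  expect_equal(r$n_iter_used + r$n_zero_denominator, 4000)
  expect_gt(r$n_zero_denominator, 0)
})

test_that("resampling is reproducible under a fixed seed", {
  branch <- setNames(rep(c("br2", "br0"), each = 20), paste0("q", 1:40))
  set.seed(3)
  comp <- setNames(sample(compartments()[1:3], 40, replace = TRUE),
                   paste0("q", 1:40))
  a1 <- colocalization_excess(branch, comp, "A", n_iter = 30, seed = 99)
  a2 <- colocalization_excess(branch, comp, "A", n_iter = 30, seed = 99)
  expect_identical(attr(a1, "iterations"), attr(a2, "iterations"))
  b1 <- colocalization_excess(branch, comp, "B", n_iter = 30, seed = 99)
  expect_false(identical(attr(a1, "iterations"), attr(b1, "iterations")))
})

test_that("branches with fewer than two proteins are skipped", {
  branch <- setNames(c("br1", rep("br0", 5)), paste0("p", 1:6))
  comp <- setNames(rep("Nucleus", 6), paste0("p", 1:6))
  res <- suppressWarnings(
    colocalization_excess(branch, comp, "A", n_iter = 5, seed = 2))
  expect_true(is.na(res$mean_excess[res$branch == "br1"]))
  expect_equal(res$n_iter_used[res$branch == "br1"], 0)
})

test_that("excess-vs-branch regression handles trend and degeneracy", {
  means <- setNames(c(1, 2, 3, 4), c("br0", "br1", "br2", "br3"))
  reg <- excess_vs_branch_regression(means)
  expect_equal(reg$r, 1)

  const <- setNames(rep(2, 4), c("br0", "br1", "br2", "br3"))
  regc <- excess_vs_branch_regression(const)
  expect_true(regc$degenerate)
  expect_true(is.na(regc$r))

  # closed-form Pearson oracle on (1,2,4,8) against branch index
  y <- c(1, 2, 4, 8)
  x <- branch_index(c("br0", "br1", "br2", "br3"))
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  reg2 <- excess_vs_branch_regression(setNames(y, c("br0", "br1", "br2",
                                                    "br3")))
  expect_equal(reg2$r, r_oracle)

  expect_error(excess_vs_branch_regression(setNames(c(1, 2), c("br0",
                                                               "br1"))),
               ">= 3")
})

test_that("co-function expectation matches hand enumeration", {
  # 4 proteins, pathways {A},{A},{B},{B}: p_co = 0.5; one group of all 4:
  # E = 6 * 0.5 = 3, O = 2 (a1-a2 and b1-b2), excess = -1/3
  pw <- list(p1 = "A", p2 = "A", p3 = "B", p4 = "B")
  groups <- setNames(rep("br1", 4), names(pw))
  res <- cofunction_expectation(pw, groups)
  expect_equal(res$p_co, 0.5)
  expect_equal(res$table$expected, 3)
  expect_equal(res$table$observed, 2)
  expect_equal(res$table$excess, -1 / 3, tolerance = 1e-12)

  # all proteins on one pathway: p_co = 1, O = E, excess 0
  pw2 <- list(p1 = "A", p2 = "A", p3 = "A")
  res2 <- cofunction_expectation(pw2, setNames(rep("g", 3), names(pw2)))
  expect_equal(res2$p_co, 1)
  expect_equal(res2$table$excess, 0)

  # expected pairs scale quadratically with group size
  pw3 <- setNames(rep(list("A"), 40), paste0("x", 1:40))
  g_small <- setNames(rep("s", 10), paste0("x", 1:10))
  g_large <- setNames(rep("l", 20), paste0("x", 1:20))
  e_small <- cofunction_expectation(pw3, g_small)$table$expected
  e_large <- cofunction_expectation(pw3, g_large)$table$expected
  expect_equal(e_large / e_small, (20 * 19) / (10 * 9))

  # order invariance of O and E
  perm <- sample(names(pw))
  res3 <- cofunction_expectation(pw[perm], groups[perm])
  expect_equal(res3$table$observed, res$table$observed)
  expect_equal(res3$table$expected, res$table$expected)

  # undersized groups are skipped with a message
  expect_message(
    out <- cofunction_expectation(pw, setNames(c("a", "b", "b", "b"),
                                               names(pw))),
    "skipping")
  expect_false("a" %in% out$table$group)
})

test_that("boosted synthetic pathways show positive co-function excess", {
  p <- simulation_params(n_genes = 1200, n_edges = 0, n_paralog_pairs = 0,
                         n_families_per_compartment = 0,
                         cofunction_boost = 3, seed = 23)
  hist <- gen_gene_history(p)
  pw <- gen_pathways(hist, p)
  groups <- setNames(hist$truth$true_branch, hist$truth$gene_id)
  big <- names(table(groups))[table(groups) >= 50]
  boosted <- setdiff(big, "br-2")
  res <- suppressMessages(cofunction_expectation(pw, groups))
  sub <- res$table[res$table$group %in% boosted, ]
  expect_true(all(sub$excess > 0))
  # the cap branch stays near baseline
  cap <- res$table[res$table$group == "br-2", ]
  expect_lt(abs(cap$excess), 0.25)
})
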