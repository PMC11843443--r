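# The seeded generator: structural contracts, determinism, recovery.

test_that("gene histories place presences by birth branch", {
  p0 <- simulation_params(n_genes = 200, n_edges = 0, n_paralog_pairs = 0,
                          n_families_per_compartment = 0, seed = 2)
  hist <- gen_gene_history(p0)
  idx <- branch_index(hist$truth$true_branch)
  clade_idx <- branch_index(hist$clades$implied_branch)
  # with no loss, presence covers exactly the clades diverging after birth
  for (i in seq_len(nrow(hist$truth))) {
    expect_equal(unname(hist$presence[i, ]), clade_idx >= idx[i])
  }
  # the cap branch is present everywhere, br6 nowhere
  oldest <- which(hist$truth$true_branch == "br-2")
  if (length(oldest) > 0) expect_true(all(hist$presence[oldest, ]))
  youngest <- which(hist$truth$true_branch == "br6")
  if (length(youngest) > 0) expect_false(any(hist$presence[youngest, ]))

  # loss probability one wipes the matrix
  p1 <- simulation_params(n_genes = 50, outgroup_loss_prob = 1, seed = 2)
  expect_false(any(gen_gene_history(p1)$presence))

  # zero genes -> empty matrix
  pe <- simulation_params(n_genes = 0, seed = 2)
  expect_equal(nrow(gen_gene_history(pe)$presence), 0)
})

test_that("perfect recovery without loss, degraded recovery with loss", {
  recovery <- function(loss, seed) {
    p <- simulation_params(n_genes = 600, outgroup_loss_prob = loss,
                           seed = seed)
    hist <- gen_gene_history(p)
    ages <- assign_ages(hist$presence, hist$clades)
    mean(ages[hist$truth$gene_id] == hist$truth$true_branch)
  }
  expect_equal(recovery(0, 31), 1)
  r <- vapply(c(0, 0.1, 0.3), recovery, numeric(1), seed = 31)
  expect_true(all(diff(r) <= 0))  # recovery degrades with loss
})

test_that("localization generator honors the labeling contracts", {
  p <- simulation_params(n_genes = 300, multi_label_rate = 0, seed = 4)
  hist <- gen_gene_history(p)
  locs <- gen_localizations(hist, p)
  m <- as.matrix(locs$localization[, compartments()])
  expect_true(all(rowSums(m > 0.5) == 1))

  # point-mass preference sends every young protein to one compartment
  pref <- uniform_compartment_preference()
  pref["young", ] <- 0
  pref["young", "Extracellular"] <- 1
  p2 <- simulation_params(n_genes = 300, compartment_preference = pref,
                          multi_label_rate = 0, seed = 4)
  locs2 <- gen_localizations(gen_gene_history(p2), p2)
  young <- branch_to_age_class(gen_gene_history(p2)$truth$true_branch) ==
    "young"
  young_called <- locs2$called[young]
  expect_true(all(vapply(young_called, identical, logical(1),
                         "Extracellular")))
})

test_that("generators are bit-reproducible under a fixed seed", {
  p <- simulation_params(n_genes = 150, n_edges = 300,
                         n_paralog_pairs = 20,
                         n_families_per_compartment = 3, seed = 77)
  s1 <- simulate_dataset(p)
  s2 <- simulate_dataset(p)
  expect_identical(s1$localization, s2$localization)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$pathways, s2$pathways)
  expect_identical(s1$pairs, s2$pairs)
})

test_that("edge sampling responds to the within-compartment preference", {
  base <- simulation_params(n_genes = 250, n_edges = 1500, seed = 12)
  hist <- gen_gene_history(base)
  locs <- gen_localizations(hist, base)
  called <- locs$called
  wc_frac <- function(pref) {
    p <- base
    p$within_edge_preference <- pref
    edges <- gen_ppi(called, p)
    mean(mapply(function(a, b) {
      length(intersect(called[[a]], called[[b]])) > 0
    }, edges$protein_a, edges$protein_b))
  }
  # pref = 1: empirical fraction near the closed-form random expectation
  ids <- names(called)
  pairs_wc <- 0
  n <- length(ids)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(called[[ids[i]]], called[[ids[j]]])) > 0) {
        pairs_wc <- pairs_wc + 1
      }
    }
  }
  p_expect <- pairs_wc / (n * (n - 1) / 2)
  f1 <- wc_frac(1)
  se <- sqrt(p_expect * (1 - p_expect) / 1500)
  expect_lt(abs(f1 - p_expect), 4 * se)
  # monotone non-decreasing in the preference (fixed seed ladder)
  f5 <- wc_frac(5)
  f50 <- wc_frac(50)
  expect_true(f1 <= f5 && f5 <= f50)
  # infinite preference: every edge within-compartment
  expect_equal(wc_frac(Inf), 1)
  # degenerate sizes
  p0 <- base
  p0$n_edges <- 0
  expect_equal(nrow(gen_ppi(called, p0)), 0)
  p_big <- base
  p_big$n_edges <- n * (n - 1) / 2 + 1
  expect_error(gen_ppi(called, p_big), "exceeds")
})

test_that("pathway generator hits the uniform baseline when unboosted", {
  p <- simulation_params(n_genes = 2500, n_pathways = 2,
                         cofunction_boost = 1, seed = 9)
  hist <- gen_gene_history(p)
  pw <- unlist(gen_pathways(hist, p))
  # two equiprobable pathways: random-pair co-function frequency ~ 0.5
  tab <- table(pw)
  p_co <- sum((tab / sum(tab))^2)
  expect_lt(abs(p_co - 0.5), 0.01)

  p1 <- simulation_params(n_genes = 100, n_pathways = 1, seed = 9)
  pw1 <- unlist(gen_pathways(gen_gene_history(p1), p1))
  expect_equal(length(unique(pw1)), 1)  # every pair co-functional

  p_err <- simulation_params(n_genes = 10, seed = 9)
  p_err$n_pathways <- 0
  expect_error(gen_pathways(gen_gene_history(p_err), p_err), "n_pathways")
})

test_that("paralog generator realizes designated patterns", {
  mixes <- c(K = 1, SE = 0, S = 0, E = 0, KE = 0)
  p <- simulation_params(n_genes = 400, n_paralog_pairs = 30,
                         n_families_per_compartment = 0,
                         paralog_pattern_mix = mixes,
                         paralog_sub_rate = 0, seed = 13)
  hist <- gen_gene_history(p)
  locs <- gen_localizations(hist, p)
  para <- gen_paralogs_and_sequences(hist, locs$called, p)
  expect_true(all(para$pairs$true_pattern == "K"))
  # zero substitution rate: identical sequences, similarity 1 downstream
  for (i in seq_len(nrow(para$pairs))) {
    expect_identical(para$sequences[[para$pairs$parent[i]]],
                     para$sequences[[para$pairs$offspring[i]]])
  }

  # designated-E pairs get disjoint localization sets
  pe <- simulation_params(n_genes = 400, n_paralog_pairs = 25,
                          n_families_per_compartment = 0,
                          paralog_pattern_mix = c(K = 0, SE = 0, S = 0,
                                                  E = 1, KE = 0),
                          seed = 13)
  hist_e <- gen_gene_history(pe)
  locs_e <- gen_localizations(hist_e, pe)
  para_e <- gen_paralogs_and_sequences(hist_e, locs_e$called, pe)
  called_e <- locs_e$called
  for (nm in names(para_e$localization_overrides)) {
    called_e[[nm]] <- para_e$localization_overrides[[nm]]
  }
  for (i in seq_len(nrow(para_e$pairs))) {
    expect_length(intersect(called_e[[para_e$pairs$parent[i]]],
                            called_e[[para_e$pairs$offspring[i]]]), 0)
  }
})

test_that("loss correction restores recovery for the older branch", {
  # loss confined to the br-1 clade, secondary outgroup intact
  p <- simulation_params(
    n_genes = 800,
    outgroup_loss_prob = setNames(c(0, 0.4, rep(0, 6)),
                                  default_clade_map()$clade_id),
    secondary_loss_prob = 0, seed = 19)
  hist <- gen_gene_history(p)
  ages <- assign_ages(hist$presence, hist$clades)
  truth <- setNames(hist$truth$true_branch, hist$truth$gene_id)
  br1_genes <- names(truth)[truth == "br-1"]
  rec_before <- mean(ages[br1_genes] == "br-1")
  corr <- apply_loss_correction(ages, hist$secondary_presence,
                                "br0", "br-1")
  rec_after <- mean(corr$ages[br1_genes] == "br-1")
  expect_gte(rec_after, rec_before)
  expect_gt(corr$n_moved, 0)
})
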