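# Greedy clustering, cluster filters, and the D statistic.

test_that("greedy clustering groups by identity over the shorter sequence", {
  s <- c(a = "MKVLAAAA", b = "MKVLAAAA")
  cl <- greedy_cluster(s)
  expect_equal(length(unique(cl$cluster_id)), 1)

  s2 <- c(a = "MKVLAAAA", b = "WWWWCCCC")
  cl2 <- greedy_cluster(s2)
  expect_equal(length(unique(cl2$cluster_id)), 2)

  # a and b match at >= 0.5, c matches neither
  s3 <- c(a = "MKVLHEAA", b = "MKVLHEWW", c = "GGGPPPTT")
  cl3 <- greedy_cluster(s3)
  groups <- split(cl3$seq_id, cl3$cluster_id)
  expect_equal(length(groups), 2)
  expect_true(any(vapply(groups, setequal, logical(1), c("a", "b"))))

  expect_equal(nrow(greedy_cluster(character())), 0)
})

test_that("greedy clustering equals the all-pairs replay oracle", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (trial in 1:3) {
    # families of related sequences plus singletons
    base1 <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    base2 <- paste(sample(aa, 24, replace = TRUE), collapse = "")
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(seq_along(ch), k)
      ch[pos] <- sample(aa, k, replace = TRUE)
      paste(ch, collapse = "")
    }
    seqs <- c(f1 = base1, f2 = mut(base1, 4), f3 = mut(base1, 6),
              g1 = base2, g2 = mut(base2, 3),
              s1 = paste(sample(aa, 27, replace = TRUE), collapse = ""))
    got <- split(greedy_cluster(seqs)$seq_id,
                 greedy_cluster(seqs)$cluster_id)
    oracle <- oracle_greedy_cluster(seqs)
    norm <- function(x) unname(lapply(x, sort))
    expect_setequal(norm(got), norm(oracle))
  }
})

test_that("cluster filters apply the membership and compartment rules", {
  clusters <- data.frame(
    seq_id = c("a", "b", "c", "d", "e", "f", "g"),
    cluster_id = c("c1", "c1", "c2", "c3", "c3", "c4", "c4"),
    representative = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  called <- make_called(a = "Nucleus", b = "Nucleus", c = "Nucleus",
                        d = c("Nucleus", "Cytoplasm"), e = "Nucleus",
                        f = "Nucleus", g = "Cytoplasm")
  res <- filter_clusters(clusters, called, min_clusters = 0)
  expect_equal(res$clusters$cluster_id, "c1")      # only all-same survives
  expect_equal(unname(res$attrition["too_small"]), 1)        # c2 singleton
  expect_equal(unname(res$attrition["multi_localized"]), 1)  # c3 has d
  expect_equal(unname(res$attrition["mixed_compartment"]), 1)  # c4 mixed

  # a compartment with exactly min_clusters clusters is dropped (strict)
  res40 <- filter_clusters(clusters, called, min_clusters = 1)
  expect_equal(nrow(res40$clusters), 0)
  expect_equal(unname(res40$attrition["rare_compartment"]), 1)
})

test_that("average pairwise divergence matches hand counts", {
  expect_equal(average_pairwise_divergence(c("ACDE", "ACDE")), 0)
  expect_equal(average_pairwise_divergence(c("AAAA", "AAAT")), 0.25)
  # triple with pairwise divergences 0, 0.25, 0.25 -> mean 1/6
  d <- average_pairwise_divergence(c("AAAA", "AAAA", "AAAT"))
  expect_equal(d, mean(c(0, 0.25, 0.25)))
  # invariant to member ordering; bounded in [0, 1]
  set.seed(5)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- replicate(4, paste(sample(aa, 15, replace = TRUE),
                             collapse = ""))
  d1 <- average_pairwise_divergence(seqs)
  d2 <- average_pairwise_divergence(rev(seqs))
  expect_equal(d1, d2)
  expect_true(d1 >= 0 && d1 <= 1)
  expect_error(average_pairwise_divergence("AAAA"), ">= 2")
})

test_that("age-constrained subsetting keeps pure deep-branch clusters", {
  clusters <- data.frame(cluster_id = c("c1", "c2"),
                         compartment = "Nucleus", n_members = 2:3)
  clusters$members <- list(c("a", "b"), c("c", "d", "e"))
  age <- c(a = "oldest", b = "oldest", c = "oldest", d = "oldest",
           e = "old")
  kept <- age_constrained_subset(clusters, age)
  expect_equal(kept$cluster_id, "c1")     # c2 has 10%+ outside allowed
  expect_equal(nrow(age_constrained_subset(clusters, age,
                                           allowed = character())), 0)
})

test_that("elevated extracellular substitution rate yields highest D", {
  p <- simulation_params(n_genes = 1200, n_edges = 0, n_paralog_pairs = 0,
                         n_families_per_compartment = 12, seed = 29)
  sim <- simulate_dataset(p)
  cl <- greedy_cluster(sim$sequences)
  filt <- filter_clusters(cl, sim$called, min_clusters = 5)
  cd <- cluster_divergence(filt$clusters, sim$sequences)
  cmp <- compare_compartment_divergence(cd)
  s <- cmp$summary
  expect_gt(nrow(s), 1)
  expect_equal(s$compartment[which.max(s$mean_D)], "Extracellular")
  # rank-sum tests flag the extracellular shift
  ex_tests <- cmp$tests[cmp$tests$compartment_a == "Extracellular" |
                          cmp$tests$compartment_b == "Extracellular", ]
  expect_true(all(ex_tests$p_value < 0.05))

  # identical D multisets are not significant
  fake <- data.frame(compartment = rep(c("Nucleus", "Cytoplasm"), each = 5),
                     D = rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 2))
  cmp2 <- compare_compartment_divergence(fake)
  expect_true(all(cmp2$tests$p_value > 0.9))

  # a single compartment leaves the test table empty
  solo <- data.frame(compartment = "Nucleus", D = c(0.1, 0.2))
  expect_equal(nrow(compare_compartment_divergence(solo)$tests), 0)
})
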