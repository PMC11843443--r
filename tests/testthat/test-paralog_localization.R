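# Duplication-age and localization-change classification.

test_that("duplication age follows the deep-branch rule", {
  expect_equal(classify_duplication("br-2", "br0"), "ancient")
  expect_equal(classify_duplication("br-1", "br0"), "ancient")
  expect_equal(classify_duplication("br0", "br3"), "recent")
  expect_error(classify_duplication("br3", "br3"), "older")
  expect_error(classify_duplication("br3", "br0"), "older")

  # exactly 3 of the 36 ordered older-parent pairs are ancient
  labs <- branch_labels()
  n_ancient <- 0
  for (i in 1:8) {
    for (j in (i + 1):9) {
      if (classify_duplication(labs[i], labs[j]) == "ancient") {
        n_ancient <- n_ancient + 1
      }
    }
  }
  expect_equal(n_ancient, 3)
})

test_that("change classification matches the five set relations", {
  expect_equal(classify_change("Nucleus", "Nucleus"), "K")
  expect_equal(classify_change("Nucleus", c("Nucleus", "Extracellular")),
               "KE")
  expect_equal(classify_change(c("Nucleus", "Cytoplasm"), "Nucleus"), "S")
  expect_equal(classify_change("Nucleus", "Extracellular"), "E")
  expect_equal(classify_change(c("Nucleus", "Cytoplasm"),
                               c("Cytoplasm", "Extracellular")), "SE")
  expect_error(classify_change(character(0), "Nucleus"), "empty")
})

test_that("the five labels partition random non-empty set pairs", {
  set.seed(14)
  cps <- compartments()
  for (i in 1:2000) {
    p <- sample(cps, sample(1:9, 1))
    o <- sample(cps, sample(1:9, 1))
    lab <- classify_change(p, o)
    # each label's defining relation must hold, and only that label fires
    relations <- c(
      K = setequal(p, o),
      KE = all(p %in% o) && !setequal(p, o),
      S = all(o %in% p) && !setequal(p, o),
      E = length(intersect(p, o)) == 0,
      SE = length(intersect(p, o)) > 0 && !all(p %in% o) &&
        !all(o %in% p))
    expect_equal(sum(relations), 1)
    expect_true(relations[[lab]])
  }
})

test_that("pair orientation enforces age polarity and one-to-one", {
  pairs <- data.frame(
    gene_id = c("a", "b", "c", "c", "f"),
    paralog_id = c("x", "y", "z", "w", "g"))
  ages <- c(a = "br0", x = "br3", b = "br2", y = "br0", c = "br0",
            z = "br1", w = "br2", f = "br4", g = "br4")
  res <- orient_paralog_pairs(pairs, ages)
  # c participates twice -> both pairs dropped; f-g same branch -> dropped
  expect_equal(nrow(res$pairs), 2)
  expect_equal(unname(res$attrition["not_one_to_one"]), 2)
  expect_equal(unname(res$attrition["same_branch"]), 1)
  # orientation puts the older gene as parent
  ab <- res$pairs[res$pairs$offspring == "x", ]
  expect_equal(ab$parent, "a")
  by <- res$pairs[res$pairs$parent == "y", ]
  expect_equal(by$offspring, "b")
})

test_that("pattern spectrum percentages tally and sum to 100", {
  pairs <- data.frame(pattern = c("K", "K", "E", "SE"),
                      duplication_age = c("recent", "recent", "ancient",
                                          "recent"))
  sp <- pattern_spectrum(pairs)
  all_row <- sp[sp$stratum == "all", ]
  expect_equal(all_row$percent[all_row$pattern == "K"], 50)
  expect_equal(all_row$percent[all_row$pattern == "E"], 25)
  expect_equal(all_row$percent[all_row$pattern == "SE"], 25)
  expect_equal(sum(all_row$percent), 100)
  expect_equal(sum(sp$percent[sp$stratum == "recent"]), 100)
  # invariant to pair ordering
  sp2 <- pattern_spectrum(pairs[c(3, 1, 4, 2), ])
  expect_equal(sp2$percent, sp$percent)
  # all-K case
  spk <- pattern_spectrum(data.frame(pattern = rep("K", 4),
                                     duplication_age = "recent"))
  expect_equal(spk$percent[spk$stratum == "all" & spk$pattern == "K"], 100)
})

test_that("K pairs show higher identity and fewer N-terminal mutations", {
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function() paste(sample(aa, 60, replace = TRUE), collapse = "")
  # K pairs: two substitutions in the middle/C-terminal region; non-K:
  # many, placed in the N-terminal third (positions fixed, not drawn, so
  # the contrast is built in by construction)
  seqs <- character()
  rows <- list()
  for (i in 1:12) {
    s <- mk()
    ch <- strsplit(s, "")[[1]]
    if (i <= 6) {
      pos <- c(30, 55)
      pat <- "K"
    } else {
      pos <- c(2, 5, 8, 11, 14, 17, 20, 45)
      pat <- "E"
    }
    ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(aa, x), 1), "")
    par <- paste0("par", i)
    off <- paste0("off", i)
    seqs[par] <- s
    seqs[off] <- paste(ch, collapse = "")
    rows[[i]] <- data.frame(parent = par, offspring = off, pattern = pat)
  }
  pairs <- do.call(rbind, rows)
  res <- k_vs_nonk_comparison(pairs, seqs)
  expect_lt(res$similarity_p, 0.05)
  expect_lt(res$position_p, 0.05)
  nt_frac <- res$bins[, "n_terminal"] / rowSums(res$bins)
  expect_gt(nt_frac["non-K"], nt_frac["K"])

  # identical sequences in both groups: no similarity signal
  seqs2 <- c(p1 = "MKVLH", o1 = "MKVLH", p2 = "ACDEF", o2 = "ACDEF")
  pairs2 <- data.frame(parent = c("p1", "p2"), offspring = c("o1", "o2"),
                       pattern = c("K", "E"))
  res2 <- k_vs_nonk_comparison(pairs2, seqs2)
  expect_gt(res2$similarity_p, 0.2)

  # pairs without sequences are dropped with a message
  pairs3 <- rbind(pairs2, data.frame(parent = "p3", offspring = "o3",
                                     pattern = "K"))
  expect_message(res3 <- k_vs_nonk_comparison(pairs3, seqs2), "dropping")
  expect_equal(res3$n_dropped, 1)
})
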