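# Duplication-age classification, K/SE/S/E/KE localization-change
# classification, and the K vs non-K sequence comparisons.

#' Classify a duplication event as ancient or recent
#'
#' Ancient duplications are the three deep-branch configurations
#' (parent br-2 with offspring br-1 or br0, or parent br-1 with offspring
#' br0); every other pair with a strictly older parent is recent.
#'
#' @param parent_branch,offspring_branch Branch labels (vectorized).
#' @return Character vector of `"ancient"` / `"recent"`.
#' @export
classify_duplication <- function(parent_branch, offspring_branch) {
  pi <- branch_index(parent_branch)
  oi <- branch_index(offspring_branch)
  if (any(pi >= oi)) {
    stop("parent branch must be strictly older than offspring branch")
  }
  p <- as.character(parent_branch)
  o <- as.character(offspring_branch)
  ancient <- (p == "br-2" & o %in% c("br-1", "br0")) |
    (p == "br-1" & o == "br0")
  ifelse(ancient, "ancient", "recent")
}

#' Classify the localization change of a paralog pair
#'
#' Given the parental call set P and offspring call set O (both non-empty):
#' `K` (kept) when O = P; `KE` (kept and extended) when P is a proper
#' subset of O; `S` (shrunk) when O is a proper subset of P; `E`
#' (exchanged) when O and P are disjoint; `SE` (shrunk and extended)
#' otherwise — partial overlap with both gain and loss. The five labels
#' partition all non-empty set pairs.
#'
#' @param parent_set,offspring_set Character vectors of compartments.
#' @return One of `"K"`, `"KE"`, `"S"`, `"E"`, `"SE"`.
#' @export
classify_change <- function(parent_set, offspring_set) {
  p <- unique(parent_set)
  o <- unique(offspring_set)
  if (length(p) == 0 || length(o) == 0) {
    stop("empty localization set; pair cannot be classified")
  }
  if (setequal(p, o)) return("K")
  if (all(p %in% o)) return("KE")
  if (all(o %in% p)) return("S")
  if (length(intersect(p, o)) == 0) return("E")
  "SE"
}

#' Orient and filter paralog pairs
#'
#' Joins raw paralog pairs to gene ages, drops pairs whose genes share a
#' branch (parent must be strictly older; count logged), enforces the
#' one-to-one filter (any gene participating in more than one pair is
#' dropped with its pairs), and orients each pair parent/offspring.
#'
#' @param pairs data.frame with columns `gene_id`, `paralog_id`.
#' @param ages Named character vector of branch labels per gene.
#' @return list with `pairs` (data.frame: parent, offspring,
#'   parent_branch, offspring_branch, duplication_age) and `attrition`
#'   (named counts: missing_age, same_branch, not_one_to_one).
#' @export
orient_paralog_pairs <- function(pairs, ages) {
  n0 <- nrow(pairs)
  has_age <- pairs$gene_id %in% names(ages) &
    pairs$paralog_id %in% names(ages)
  missing_age <- sum(!has_age)
  pairs <- pairs[has_age, , drop = FALSE]

  # one-to-one: drop genes appearing in more than one pair
  all_genes <- c(pairs$gene_id, pairs$paralog_id)
  multi <- unique(all_genes[duplicated(all_genes)])
  in_multi <- pairs$gene_id %in% multi | pairs$paralog_id %in% multi
  not_one_to_one <- sum(in_multi)
  pairs <- pairs[!in_multi, , drop = FALSE]

  b1 <- branch_index(ages[pairs$gene_id])
  b2 <- branch_index(ages[pairs$paralog_id])
  same <- b1 == b2
  same_branch <- sum(same)
  pairs <- pairs[!same, , drop = FALSE]
  b1 <- b1[!same]
  b2 <- b2[!same]

  parent <- ifelse(b1 < b2, pairs$gene_id, pairs$paralog_id)
  offspring <- ifelse(b1 < b2, pairs$paralog_id, pairs$gene_id)
  out <- data.frame(parent = parent, offspring = offspring,
                    parent_branch = as.character(ages[parent]),
                    offspring_branch = as.character(ages[offspring]),
                    stringsAsFactors = FALSE)
  out$duplication_age <- if (nrow(out) > 0) {
    classify_duplication(out$parent_branch, out$offspring_branch)
  } else character(0)
  rownames(out) <- NULL
  list(pairs = out,
       attrition = c(missing_age = missing_age,
                     same_branch = same_branch,
                     not_one_to_one = not_one_to_one),
       n_input = n0)
}

#' Classify localization changes for oriented paralog pairs
#'
#' @param pairs data.frame from [orient_paralog_pairs()]`$pairs`.
#' @param called Named list of called-compartment vectors per gene
#'   (longest-transcript representative).
#' @return The pairs data.frame with a `pattern` column; pairs with an
#'   empty or missing call set on either side are dropped (count in the
#'   `n_unclassifiable` attribute).
#' @export
classify_pair_changes <- function(pairs, called) {
  ok <- pairs$parent %in% names(called) & pairs$offspring %in% names(called)
  ok[ok] <- lengths(called[pairs$parent[ok]]) > 0 &
    lengths(called[pairs$offspring[ok]]) > 0
  dropped <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  pairs$pattern <- vapply(seq_len(nrow(pairs)), function(i) {
    classify_change(called[[pairs$parent[i]]],
                    called[[pairs$offspring[i]]])
  }, character(1))
  attr(pairs, "n_unclassifiable") <- dropped
  pairs
}

#' Pattern spectrum of localization changes
#'
#' Percentage of pairs per change pattern, overall and per duplication-age
#' stratum. Percentages within a stratum sum to 100.
#'
#' @param pairs data.frame with `pattern` and `duplication_age` columns.
#' @return data.frame with columns `stratum` (`all`, `ancient`, `recent`),
#'   `pattern`, `n`, `percent`; strata with no pairs are flagged with NA
#'   percentages.
#' @export
pattern_spectrum <- function(pairs) {
  patterns <- c("K", "SE", "S", "E", "KE")
  strata <- list(all = rep(TRUE, nrow(pairs)),
                 ancient = pairs$duplication_age == "ancient",
                 recent = pairs$duplication_age == "recent")
  rows <- lapply(names(strata), function(s) {
    sub <- pairs$pattern[strata[[s]]]
    n <- table(factor(sub, levels = patterns))
    data.frame(stratum = s, pattern = patterns, n = as.integer(n),
               percent = if (length(sub) > 0)
                 100 * as.integer(n) / length(sub) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sequence comparisons between K and non-K pairs
#'
#' Aligns each pair's protein sequences globally; compares per-pair global
#' identity between the K group and the pooled non-K group with a one-sided
#' (greater) Mann-Whitney test, and compares the pooled relative mutation
#' positions with a two-sided Mann-Whitney test. Mutation positions are
#' additionally summarized into N-terminal / middle / C-terminal thirds.
#'
#' @param pairs data.frame with `parent`, `offspring`, `pattern` columns.
#' @param seqs Named character vector of protein sequences per gene.
#' @return list with `pair_stats` (per-pair data.frame: parent, offspring,
#'   pattern, group, identity, n_mutations), `similarity_p` (one-sided,
#'   K > non-K), `position_p` (two-sided), `bins` (2x3 counts by group),
#'   `n_dropped` (pairs missing a sequence).
#' @export
k_vs_nonk_comparison <- function(pairs, seqs) {
  ok <- pairs$parent %in% names(seqs) & pairs$offspring %in% names(seqs)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message("k_vs_nonk_comparison: dropping ", n_dropped,
            " pair(s) without sequences")
  }
  pairs <- pairs[ok, , drop = FALSE]
  group <- ifelse(pairs$pattern == "K", "K", "non-K")
  identity <- numeric(nrow(pairs))
  positions <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    aln <- global_align(seqs[[pairs$parent[i]]],
                        seqs[[pairs$offspring[i]]])
    identity[i] <- aln$identity
    positions[[i]] <- aln$mutation_positions
  }
  pair_stats <- data.frame(parent = pairs$parent,
                           offspring = pairs$offspring,
                           pattern = pairs$pattern, group = group,
                           identity = identity,
                           n_mutations = lengths(positions),
                           stringsAsFactors = FALSE)
  pos_k <- unlist(positions[group == "K"])
  pos_n <- unlist(positions[group == "non-K"])
  sim_p <- if (sum(group == "K") > 0 && sum(group == "non-K") > 0) {
    suppressWarnings(wilcox.test(identity[group == "K"],
                                 identity[group == "non-K"],
                                 alternative = "greater")$p.value)
  } else NA_real_
  pos_p <- if (length(pos_k) > 0 && length(pos_n) > 0) {
    suppressWarnings(wilcox.test(pos_k, pos_n)$p.value)
  } else NA_real_
  bins <- rbind(K = mutation_position_bins(pos_k %||% numeric(0)),
                `non-K` = mutation_position_bins(pos_n %||% numeric(0)))
  list(pair_stats = pair_stats, similarity_p = sim_p, position_p = pos_p,
       bins = bins, n_dropped = n_dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
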