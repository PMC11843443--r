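# Greedy identity clustering, cluster filters, and the average pairwise
# divergence (D value) per subcellular compartment.

# 3-mer set of a sequence, for the shared-word prefilter.
.kmer_set <- function(seq, k = 3) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy incremental sequence clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted by decreasing
#' length (ties by id) and each sequence joins the first existing cluster
#' whose representative (founder) it matches at identity >=
#' `identity_threshold`, where identity is identical aligned positions
#' divided by the shorter sequence length. Sequences matching no cluster
#' found a new one. A shared-word prefilter skips the alignment when the
#' two sequences share no `word_length`-mer. Only the greedy core and the
#' word prefilter of CD-HIT are reproduced; its banded-alignment heuristics
#' are not.
#'
#' @param seqs Named character vector of protein sequences (one
#'   representative per gene).
#' @param identity_threshold Minimum identity to join a cluster
#'   (default 0.5).
#' @param word_length Length of the shared-word prefilter (default 3).
#' @return data.frame with columns `seq_id`, `cluster_id`,
#'   `representative` (logical); empty input gives zero rows.
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.5, word_length = 3) {
  if (length(seqs) == 0) {
    return(data.frame(seq_id = character(), cluster_id = character(),
                      representative = logical(), stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ids <- names(seqs)
  rep_idx <- integer()          # indices (into seqs) of cluster founders
  rep_words <- list()
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    w <- .kmer_set(seqs[i], word_length)
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      if (length(w) > 0 && !any(w %in% rep_words[[ci]])) next
      idty <- identity_over_shorter(seqs[i], seqs[rep_idx[ci]])
      if (idty >= identity_threshold) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      rep_words <- c(rep_words, list(w))
      assignment[i] <- length(rep_idx)
    }
  }
  data.frame(seq_id = ids,
             cluster_id = sprintf("cluster_%04d", assignment),
             representative = seq_along(seqs) %in% rep_idx,
             stringsAsFactors = FALSE)
}

#' Filter clusters for divergence analysis
#'
#' Keeps clusters with at least two members whose members are all localized
#' to a single, common compartment, then keeps only compartments with
#' strictly more than `min_clusters` surviving clusters.
#'
#' @param clusters data.frame from [greedy_cluster()].
#' @param called Named list of called-compartment vectors per sequence id.
#' @param min_members Minimum cluster size (default 2).
#' @param min_clusters A compartment must have more than this many
#'   surviving clusters to be retained (default 40, strict).
#' @param require_same_compartment If `TRUE` (default) all members must be
#'   single-localized to the same compartment; `FALSE` relaxes to
#'   single-localized members without requiring a shared compartment (such
#'   clusters get compartment NA and are dropped from per-compartment
#'   comparisons).
#' @return list with `clusters` (data.frame: cluster_id, compartment,
#'   n_members, members list column) and `attrition` (named counts of
#'   dropped clusters per rule).
#' @export
filter_clusters <- function(clusters, called, min_members = 2,
                            min_clusters = 40,
                            require_same_compartment = TRUE) {
  stopifnot(all(clusters$seq_id %in% names(called)))
  split_members <- split(clusters$seq_id, clusters$cluster_id)
  attrition <- c(too_small = 0L, multi_localized = 0L,
                 mixed_compartment = 0L, rare_compartment = 0L)
  rows <- list()
  for (cid in names(split_members)) {
    members <- split_members[[cid]]
    if (length(members) < min_members) {
      attrition["too_small"] <- attrition["too_small"] + 1L
      next
    }
    sets <- called[members]
    if (any(lengths(sets) != 1)) {
      attrition["multi_localized"] <- attrition["multi_localized"] + 1L
      next
    }
    comps <- unique(unlist(sets, use.names = FALSE))
    if (length(comps) > 1) {
      if (require_same_compartment) {
        attrition["mixed_compartment"] <- attrition["mixed_compartment"] + 1L
        next
      }
      comps <- NA_character_
    }
    r <- data.frame(cluster_id = cid, compartment = comps,
                    n_members = length(members), stringsAsFactors = FALSE)
    r$members <- list(members)
    rows[[length(rows) + 1L]] <- r
  }
  kept <- do.call(rbind, rows)
  if (is.null(kept)) {
    kept <- data.frame(cluster_id = character(), compartment = character(),
                       n_members = integer(), stringsAsFactors = FALSE)
    kept$members <- list()
    return(list(clusters = kept, attrition = attrition))
  }
  comp_counts <- table(kept$compartment)
  rare <- names(comp_counts)[comp_counts <= min_clusters]
  attrition["rare_compartment"] <- sum(kept$compartment %in% rare)
  kept <- kept[!(kept$compartment %in% rare), , drop = FALSE]
  rownames(kept) <- NULL
  list(clusters = kept, attrition = attrition)
}

#' Average pairwise divergence of a cluster
#'
#' Every unordered member pair is globally aligned; per-pair divergence is
#' the number of differing columns divided by the number of columns where
#' both sequences carry a residue (indel columns excluded). D is the mean
#' over pairs. The divergence definition (mismatches over mutually resolved
#' columns) is normative for this package.
#'
#' @param member_seqs Character vector of >= 2 member sequences.
#' @return Numeric D in [0, 1].
#' @export
average_pairwise_divergence <- function(member_seqs) {
  n <- length(member_seqs)
  if (n < 2) stop("need >= 2 member sequences")
  divs <- numeric(0)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(member_seqs[i], member_seqs[j])
      mism <- length(aln$mutation_positions)
      resolved <- aln$n_matches + mism  # columns where both carry a residue
      divs <- c(divs, if (resolved > 0) mism / resolved else 0)
    }
  }
  mean(divs)
}

#' Restrict clusters to given age classes
#'
#' Keeps only clusters whose member composition lies entirely inside the
#' allowed age classes, removing the confounding of divergence by
#' origination time.
#'
#' @param clusters Filtered cluster data.frame (see [filter_clusters()]).
#' @param age_class Named character vector of age classes per sequence id.
#' @param allowed Age classes a cluster may contain (default the two
#'   deepest, `oldest` and `older`).
#' @return Subset of `clusters`.
#' @export
age_constrained_subset <- function(clusters, age_class,
                                   allowed = c("oldest", "older")) {
  if (nrow(clusters) == 0 || length(allowed) == 0) {
    return(clusters[0, , drop = FALSE])
  }
  keep <- vapply(clusters$members, function(m) {
    cls <- age_class[m]
    !anyNA(cls) && all(cls %in% allowed)
  }, logical(1))
  out <- clusters[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute D for each filtered cluster
#'
#' @param clusters Filtered cluster data.frame (see [filter_clusters()]).
#' @param seqs Named character vector of sequences covering all members.
#' @return The input data.frame with a numeric `D` column appended.
#' @export
cluster_divergence <- function(clusters, seqs) {
  clusters$D <- vapply(clusters$members, function(m) {
    average_pairwise_divergence(unname(seqs[m]))
  }, numeric(1))
  clusters
}

#' Compare D distributions across compartments
#'
#' Per-compartment summary of cluster D values plus all-pairs two-sided
#' Mann-Whitney (Wilcoxon rank-sum) tests. Compartments with fewer than two
#' clusters are excluded from testing.
#'
#' @param cluster_d data.frame with `compartment` and `D` columns (see
#'   [cluster_divergence()]).
#' @return list with `summary` (compartment, n_clusters, mean_D, median_D)
#'   and `tests` (compartment_a, compartment_b, p_value); `tests` has zero
#'   rows when fewer than two compartments qualify.
#' @export
compare_compartment_divergence <- function(cluster_d) {
  cluster_d <- cluster_d[!is.na(cluster_d$compartment), , drop = FALSE]
  comp <- split(cluster_d$D, cluster_d$compartment)
  comp <- comp[lengths(comp) >= 2]
  summary <- data.frame(
    compartment = names(comp),
    n_clusters = as.integer(lengths(comp)),
    mean_D = vapply(comp, mean, numeric(1)),
    median_D = vapply(comp, median, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  tests <- data.frame(compartment_a = character(),
                      compartment_b = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  nm <- names(comp)
  if (length(nm) >= 2) {
    combos <- combn(nm, 2)
    tests <- data.frame(
      compartment_a = combos[1, ], compartment_b = combos[2, ],
      p_value = apply(combos, 2, function(p) {
        suppressWarnings(wilcox.test(comp[[p[1]]], comp[[p[2]]])$p.value)
      }), stringsAsFactors = FALSE)
  }
  list(summary = summary, tests = tests)
}
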