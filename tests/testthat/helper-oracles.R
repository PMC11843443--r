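# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: the age oracle is a literal linear scan, and the
# alignment oracle scores every monotone alignment template explicitly.

# Linear-scan parsimony oracle: walk the ordered clades and return the
# implied branch of the first (oldest-diverging) clade with a presence.
oracle_assign_age <- function(presence_row, clades) {
  for (i in seq_len(nrow(clades))) {
    if (isTRUE(presence_row[[clades$clade_id[i]]])) {
      return(clades$implied_branch[i])
    }
  }
  "br6"
}

# Enumerate all global alignment "templates" for sequence lengths (la, lb):
# move strings over D (residue-residue), U (gap in b, consumes a),
# L (gap in a, consumes b). Each template records the matched position
# pairs and the total affine gap score (first gap column gap_open, later
# columns gap_extend). Cached per length pair.
.template_cache <- new.env(parent = emptyenv())

enumerate_templates <- function(la, lb, gap_open = -10, gap_extend = -1) {
  key <- paste(la, lb, gap_open, gap_extend, sep = "_")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  paths <- list()
  walk <- function(i, j, moves) {
    if (i == la && j == lb) {
      paths[[length(paths) + 1L]] <<- moves
      return(invisible())
    }
    if (i < la && j < lb) walk(i + 1, j + 1, c(moves, "D"))
    if (i < la) walk(i + 1, j, c(moves, "U"))
    if (j < lb) walk(i, j + 1, c(moves, "L"))
  }
  walk(0, 0, character())
  templates <- lapply(paths, function(mv) {
    ii <- cumsum(mv != "L")
    jj <- cumsum(mv != "U")
    d <- mv == "D"
    runs <- rle(mv)
    gap_lens <- runs$lengths[runs$values != "D"]
    gap_score <- sum(gap_open + (gap_lens - 1) * gap_extend)
    list(ai = ii[d], bj = jj[d], gap_score = gap_score)
  })
  .template_cache[[key]] <- templates
  templates
}

# Oracle optimal-score matrix for ALL sequence pairs of fixed lengths:
# A, B are integer matrices (sequences as rows, residue codes as columns),
# sub a small substitution matrix. Returns an nrow(A) x nrow(B) matrix of
# optimal global alignment scores under the affine scheme.
oracle_score_matrix <- function(A, B, sub, gap_open = -10, gap_extend = -1) {
  la <- ncol(A)
  lb <- ncol(B)
  templates <- enumerate_templates(la, lb, gap_open, gap_extend)
  # precompute the substitution-score matrix for every (i, j) column pair
  M <- vector("list", la * lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      M[[(i - 1) * lb + j]] <- sub[A[, i], B[, j], drop = FALSE]
    }
  }
  best <- matrix(-Inf, nrow(A), nrow(B))
  zero <- matrix(0, nrow(A), nrow(B))
  for (tp in templates) {
    s <- zero + tp$gap_score
    if (length(tp$ai) > 0) {
      for (k in seq_along(tp$ai)) {
        s <- s + M[[(tp$ai[k] - 1) * lb + tp$bj[k]]]
      }
    }
    best <- pmax(best, s)
  }
  best
}

# All sequences of the given length over an alphabet, as an integer matrix
# of codes into the alphabet (rows = sequences).
all_seq_matrix <- function(len, n_alpha) {
  as.matrix(expand.grid(rep(list(seq_len(n_alpha)), len)))
}

# Render integer code rows to strings over the alphabet.
codes_to_strings <- function(codes, alphabet) {
  apply(codes, 1, function(r) paste(alphabet[r], collapse = ""))
}

# Greedy clustering replay oracle: recompute the full pairwise identity
# matrix and replay the documented greedy order explicitly.
oracle_greedy_cluster <- function(seqs, threshold = 0.5) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- integer()
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (identity_over_shorter(seqs[i], seqs[reps[ci]]) >= threshold) {
        assignment[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }
  split(names(seqs), assignment)
}
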