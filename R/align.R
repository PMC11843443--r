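# Global pairwise protein alignment, identity, and mutation-position
# extraction. Shared by the divergence and paralog modules.

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Fetched once from Biostrings and cached for the session.
#' @return Numeric substitution matrix with amino-acid dimnames.
#' @export
blosum62_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment under affine gap penalties with a
#' deterministic traceback (match/mismatch preferred over a gap in `seq_a`,
#' which is preferred over a gap in `seq_b`). A gap run of length L scores
#' `gap_open + (L - 1) * gap_extend`; end gaps are penalized.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings (standard 20 letters plus
#'   any extra letters present in the substitution matrix, e.g. `X`).
#' @param substitution_matrix Square numeric matrix with residue dimnames;
#'   defaults to BLOSUM62.
#' @param gap_open Score for the first column of a gap run (negative).
#' @param gap_extend Score for each subsequent gap column (negative).
#' @return An object of class `pairwise_alignment`: a list with elements
#'   `aligned_a`, `aligned_b` (equal-length strings, gap character `-`),
#'   `score`, `length` (alignment columns), `identity` (identical columns /
#'   alignment length), `n_matches`, and `mutation_positions` (relative
#'   positions, column / alignment length, of substituted columns; indel
#'   columns are not counted as mutations).
#' @examples
#' aln <- global_align("MKVLH", "MKILH")
#' aln$identity
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = NULL,
                         gap_open = -10, gap_extend = -1) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1, length(seq_b) == 1)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("sequences must be non-empty")
  }
  alpha <- rownames(substitution_matrix)
  ca <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  ia <- match(ca, alpha)
  ib <- match(cb, alpha)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(ca[is.na(ia)], cb[is.na(ib)]))
    stop("illegal sequence character(s): ", paste(bad, collapse = ", "))
  }
  res <- nw_align_cpp(ia, ib, substitution_matrix, gap_open, gap_extend,
                      FALSE)
  states <- res$states
  n_col <- length(states)
  col_a <- character(n_col)
  col_b <- character(n_col)
  col_a[states != 1L] <- ca
  col_a[states == 1L] <- "-"
  col_b[states != 2L] <- cb
  col_b[states == 2L] <- "-"
  both <- states == 0L
  ident <- both & col_a == col_b
  mism <- both & col_a != col_b
  out <- list(
    aligned_a = paste(col_a, collapse = ""),
    aligned_b = paste(col_b, collapse = ""),
    score = res$score,
    length = n_col,
    n_matches = sum(ident),
    identity = sum(ident) / n_col,
    mutation_positions = which(mism) / n_col
  )
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global pairwise alignment\n")
  cat("  score:    ", x$score, "\n", sep = "")
  cat("  length:   ", x$length, "\n", sep = "")
  cat("  identity: ", sprintf("%.3f", x$identity), "\n", sep = "")
  cat("  A: ", x$aligned_a, "\n", sep = "")
  cat("  B: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Alignment score only (fast path)
#'
#' @inheritParams global_align
#' @return Numeric optimal global alignment score.
#' @export
global_align_score <- function(seq_a, seq_b, substitution_matrix = NULL,
                               gap_open = -10, gap_extend = -1) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  alpha <- rownames(substitution_matrix)
  ia <- match(strsplit(toupper(seq_a), "", fixed = TRUE)[[1]], alpha)
  ib <- match(strsplit(toupper(seq_b), "", fixed = TRUE)[[1]], alpha)
  if (anyNA(ia) || anyNA(ib)) stop("illegal sequence character(s)")
  nw_align_cpp(ia, ib, substitution_matrix, gap_open, gap_extend, TRUE)$score
}

#' Percent identity over the shorter sequence
#'
#' Identity definition used by the greedy clustering step: identical aligned
#' columns divided by the length of the shorter input sequence.
#'
#' @inheritParams global_align
#' @return Numeric in [0, 1].
#' @export
identity_over_shorter <- function(seq_a, seq_b, substitution_matrix = NULL,
                                  gap_open = -10, gap_extend = -1) {
  aln <- global_align(seq_a, seq_b, substitution_matrix, gap_open, gap_extend)
  aln$n_matches / min(nchar(seq_a), nchar(seq_b))
}

#' Bin relative mutation positions into protein thirds
#'
#' Relative substitution positions (column index / alignment length) are
#' binned into N-terminal (0, 1/3], middle (1/3, 2/3] and C-terminal
#' (2/3, 1]. A position exactly at 1/3 falls in the N-terminal bin.
#'
#' @param x A `pairwise_alignment` object or a numeric vector of relative
#'   positions in (0, 1].
#' @return Named integer vector with counts `n_terminal`, `middle`,
#'   `c_terminal`.
#' @export
mutation_position_bins <- function(x) {
  pos <- if (inherits(x, "pairwise_alignment")) x$mutation_positions else x
  stopifnot(is.numeric(pos))
  if (length(pos) > 0 && (any(pos <= 0) || any(pos > 1))) {
    stop("relative positions must lie in (0, 1]")
  }
  c(n_terminal = sum(pos <= 1 / 3),
    middle = sum(pos > 1 / 3 & pos <= 2 / 3),
    c_terminal = sum(pos > 2 / 3))
}
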