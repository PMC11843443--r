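# Compartment calling from probability tables, branch-wise enrichment
# excess, three-level grouping, and localization breadth by age class.

#' Call compartments from localization probabilities
#'
#' A protein is called localized to every compartment whose probability is
#' strictly greater than the threshold; multi-membership is allowed and a
#' protein with no probability above threshold gets an empty call set.
#'
#' @param probs Either a named numeric vector over [compartments()] for one
#'   protein, or a numeric matrix/data.frame with proteins as rows and the
#'   nine compartment columns.
#' @param threshold Probability threshold (default 0.5, strict inequality).
#' @return For a vector input, a character vector of called compartments;
#'   for a matrix input, a named list of such vectors (one per row).
#' @examples
#' call_compartments(c(Cytoplasm = 0.1, Nucleus = 0.9, Extracellular = 0,
#'   Cell_membrane = 0, Mitochondrion = 0, Endoplasmic_reticulum = 0,
#'   Lysosome_Vacuole = 0, Golgi_apparatus = 0, Peroxisome = 0))
#' @export
call_compartments <- function(probs, threshold = 0.5) {
  if (is.null(dim(probs))) {
    stopifnot(all(compartments() %in% names(probs)))
    p <- probs[compartments()]
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    return(compartments()[p > threshold])
  }
  stopifnot(all(compartments() %in% colnames(probs)))
  m <- as.matrix(probs[, compartments()])
  if (any(m < 0 | m > 1)) stop("probabilities must lie in [0, 1]")
  called <- m > threshold
  ids <- if (!is.null(rownames(probs))) rownames(probs) else
    as.character(seq_len(nrow(m)))
  out <- apply(called, 1, function(r) compartments()[r], simplify = FALSE)
  setNames(out, ids)
}

#' Call sets for a localization table
#'
#' Convenience wrapper around [call_compartments()] for the data.frame
#' returned by [read_localization_table()].
#'
#' @param loc data.frame with `protein_id` and the nine compartment columns.
#' @param threshold Probability threshold (strict).
#' @return Named list of called-compartment character vectors per protein.
#' @export
localization_calls <- function(loc, threshold = 0.5) {
  m <- as.matrix(loc[, compartments()])
  rownames(m) <- loc$protein_id
  call_compartments(m, threshold)
}

#' Collapse call sets to the three-level grouping
#'
#' @param called Named list of called-compartment vectors.
#' @return Named list of subsets of
#'   `c("intracellular", "cell_membrane", "extracellular")`.
#' @export
level3_calls <- function(called) {
  lapply(called, function(s) unique(compartment_level3(s)))
}

#' Localization enrichment by branch or age class
#'
#' Compares, per (group, compartment) cell, the observed number of proteins
#' called in the compartment with the number expected if localization were
#' independent of gene age: `expected = total_compartment * n_group / N`,
#' where N counts localized proteins (proteins with an empty call set are
#' excluded from all denominators and reported separately). The excess
#' percentage is `(observed - expected) / expected * 100`. Each cell gets a
#' Fisher exact test on the 2x2 table (in/out group x in/out compartment),
#' reported raw and Benjamini-Hochberg adjusted.
#'
#' @param groups Named character/factor vector, one group label (branch or
#'   age class) per protein.
#' @param called Named list of called-compartment vectors per protein;
#'   names must cover `names(groups)`.
#' @param level `"compartment"` for the nine compartments or `"level3"` for
#'   the intracellular / cell-membrane / extracellular grouping.
#' @return list with `table` (data.frame: group, compartment, observed,
#'   expected, excess_pct, p_value, p_adj), `n_unlocalized`, and
#'   `group_sizes`. Cells in empty groups carry expected 0 and NA excess.
#' @export
enrichment <- function(groups, called, level = c("compartment", "level3")) {
  level <- match.arg(level)
  ids <- names(groups)
  if (is.null(ids) || !all(ids %in% names(called))) {
    stop("every grouped protein needs a call set")
  }
  called <- called[ids]
  if (level == "level3") called <- level3_calls(called)
  comp_levels <- if (level == "level3")
    c("intracellular", "cell_membrane", "extracellular") else compartments()

  n_called <- lengths(called)
  unlocalized <- n_called == 0
  groups <- factor(groups[!unlocalized])
  called <- called[!unlocalized]
  N <- length(called)

  grp_of <- rep(groups, lengths(called))
  comp_of <- factor(unlist(called, use.names = FALSE), levels = comp_levels)
  obs <- table(group = grp_of, compartment = comp_of)
  n_g <- table(groups)
  total_c <- colSums(obs)

  rows <- expand.grid(group = levels(groups), compartment = comp_levels,
                      stringsAsFactors = FALSE)
  rows$observed <- as.integer(obs[cbind(rows$group, rows$compartment)])
  rows$expected <- total_c[rows$compartment] *
    as.numeric(n_g[rows$group]) / N
  rows$excess_pct <- ifelse(rows$expected > 0,
                            100 * (rows$observed - rows$expected) /
                              rows$expected, NA_real_)
  rows$p_value <- vapply(seq_len(nrow(rows)), function(i) {
    a <- rows$observed[i]
    ng <- as.numeric(n_g[rows$group[i]])
    tc <- as.numeric(total_c[rows$compartment[i]])
    if (ng == 0 || N == 0) return(NA_real_)
    tab <- matrix(c(a, tc - a, ng - a, N - tc - ng + a), nrow = 2)
    fisher.test(tab)$p.value
  }, numeric(1))
  rows$p_adj <- p.adjust(rows$p_value, method = "BH")
  rownames(rows) <- NULL
  list(table = rows, n_unlocalized = sum(unlocalized),
       group_sizes = n_g)
}

#' Localization breadth by age class
#'
#' For each age class, the proportion of proteins whose call set spans more
#' than `k` subcellular compartments.
#'
#' @param called Named list of called-compartment vectors per protein.
#' @param age_class Named character/factor vector of age classes per
#'   protein (names must be covered by `called`).
#' @param k Breadth cutoffs; proportions are computed for `|set| > k`.
#' @return data.frame with columns `age_class`, `k`, `n_proteins`,
#'   `proportion` (NA-flagged for empty classes).
#' @export
breadth_by_age <- function(called, age_class, k = c(2, 3, 4)) {
  ids <- names(age_class)
  stopifnot(!is.null(ids), all(ids %in% names(called)))
  sizes <- lengths(called[ids])
  cls <- factor(age_class, levels = unique(c(age_classes(),
                                             levels(factor(age_class)))))
  cls <- droplevels(cls[match(ids, names(age_class))])
  out <- expand.grid(age_class = levels(cls), k = k,
                     stringsAsFactors = FALSE)
  out$n_proteins <- as.integer(table(cls)[out$age_class])
  out$proportion <- vapply(seq_len(nrow(out)), function(i) {
    in_cls <- cls == out$age_class[i]
    if (!any(in_cls)) return(NA_real_)
    mean(sizes[in_cls] > out$k[i])
  }, numeric(1))
  out
}
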