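# Parsimony branch assignment from syntenic-ortholog presence, gene-loss
# correction, masked-exon filtering, fixation rates, and chromosome-class
# comparisons.

#' Build a clade map
#'
#' An ordered description of the outgroup clades used for dating: oldest
#' divergence first, each clade carrying the branch label implied when it is
#' the most distant ortholog-bearing clade. Implied branches must strictly
#' increase (get younger) along the list, and the oldest clade implies the
#' cap branch `br-2`: ages are capped there.
#'
#' @param clade_id Character vector of clade identifiers, oldest first.
#' @param implied_branch Branch label implied by each clade.
#' @param species Optional list of member-species vectors per clade.
#' @return data.frame of class `clade_map` with columns `clade_id`,
#'   `implied_branch` and a `species` list column.
#' @export
clade_map <- function(clade_id, implied_branch, species = NULL) {
  stopifnot(length(clade_id) == length(implied_branch))
  if (anyDuplicated(clade_id)) stop("duplicate clade_id")
  idx <- branch_index(implied_branch)
  if (any(diff(idx) <= 0)) {
    stop("implied_branch must strictly increase (oldest divergence first)")
  }
  if (idx[1] != 1L) {
    stop("the oldest clade must imply the cap branch ", branch_labels()[1])
  }
  if (is.null(species)) species <- as.list(clade_id)
  df <- data.frame(clade_id = clade_id,
                   implied_branch = as.character(implied_branch),
                   stringsAsFactors = FALSE)
  df$species <- species
  class(df) <- c("clade_map", "data.frame")
  df
}

#' Default eight-clade map
#'
#' One outgroup clade per branch boundary of the nine-branch scale: clades
#' implying `br-2` through `br5`; genes absent everywhere are assigned the
#' species-specific branch `br6`.
#'
#' @return A `clade_map` with eight clades.
#' @export
default_clade_map <- function() {
  br <- branch_labels()[1:8]
  clade_map(clade_id = paste0("clade_", br), implied_branch = br)
}

#' Assign a branch age from an ortholog presence pattern
#'
#' Parsimony rule: the gene is as old as the oldest-diverging clade that
#' retains a syntenic ortholog. With no presence anywhere the gene is
#' species-specific (`br6`).
#'
#' @param presence_row Named logical vector covering every clade in
#'   `clades` (presence of >= 1 ortholog-bearing species in that clade).
#' @param clades A `clade_map`.
#' @return A single branch label.
#' @export
assign_age <- function(presence_row, clades) {
  missing <- setdiff(clades$clade_id, names(presence_row))
  if (length(missing) > 0) {
    stop("presence_row missing clade(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(presence_row), clades$clade_id)
  if (length(extra) > 0) {
    stop("unknown clade key(s): ", paste(extra, collapse = ", "))
  }
  pres <- as.logical(presence_row[clades$clade_id])
  hit <- which(pres)
  if (length(hit) == 0) return(branch_labels()[length(branch_labels())])
  clades$implied_branch[hit[1]]
}

#' Assign branch ages for a presence/absence matrix
#'
#' Vectorized form of [assign_age()].
#'
#' @param presence Logical matrix, genes as rows, clade ids as columns.
#' @param clades A `clade_map`.
#' @return Named character vector of branch labels per gene.
#' @export
assign_ages <- function(presence, clades) {
  missing <- setdiff(clades$clade_id, colnames(presence))
  if (length(missing) > 0) {
    stop("presence matrix missing clade(s): ",
         paste(missing, collapse = ", "))
  }
  m <- presence[, clades$clade_id, drop = FALSE]
  first_hit <- apply(m, 1, function(r) match(TRUE, r))
  br <- ifelse(is.na(first_hit),
               branch_labels()[length(branch_labels())],
               clades$implied_branch[first_hit])
  setNames(br, rownames(presence))
}

#' Correct branch assignments for outgroup gene loss
#'
#' A gene dated to `from_branch` that is nevertheless present in a secondary
#' outgroup at the `to_branch` level must have been lost in the primary
#' outgroup, so its age is pushed back to `to_branch`. Genes on other
#' branches are untouched regardless of secondary presence.
#'
#' @param ages Named character vector of branch labels per gene.
#' @param secondary_presence Named logical vector (presence in the secondary
#'   outgroup) covering at least the genes at `from_branch`.
#' @param from_branch Branch whose assignments are audited.
#' @param to_branch Older branch to move flagged genes to.
#' @return list with `ages` (corrected vector) and `n_moved`.
#' @export
apply_loss_correction <- function(ages, secondary_presence,
                                  from_branch, to_branch) {
  if (branch_index(to_branch) >= branch_index(from_branch)) {
    stop("to_branch must be older than from_branch")
  }
  at_from <- names(ages)[ages == from_branch]
  pres <- secondary_presence[at_from]
  pres[is.na(pres)] <- FALSE
  moved <- at_from[as.logical(pres)]
  ages[moved] <- to_branch
  list(ages = ages, n_moved = length(moved))
}

#' Filter genes by masked-exon fraction
#'
#' Genes whose exons are mostly repeat-masked give unreliable genome
#' alignments; genes with a masked fraction strictly greater than
#' `max_fraction` are excluded.
#'
#' @param masked_fraction Named numeric vector in [0, 1] per gene.
#' @param max_fraction Exclusion threshold (default 0.70; the boundary value
#'   itself is retained).
#' @return Character vector of retained gene ids.
#' @export
masked_exon_filter <- function(masked_fraction, max_fraction = 0.70) {
  if (any(masked_fraction < 0 | masked_fraction > 1)) {
    stop("masked fractions must lie in [0, 1]")
  }
  names(masked_fraction)[masked_fraction <= max_fraction]
}

#' Gene fixation rate on a branch
#'
#' Fixation rate = (births - deaths) / span, in genes per million years.
#' The raw rate is always retained; `reported` applies round-half-up at the
#' requested precision, matching how such rates are conventionally printed.
#'
#' @param births Number of gene births on the branch.
#' @param deaths Number of gene deaths (default 0 when uncounted; a loss-
#'   correction count can serve as a deaths estimate).
#' @param span Branch duration in million years (> 0).
#' @param digits Decimal places for the reported rate.
#' @return list with `births`, `deaths`, `span`, `rate` (raw) and
#'   `reported` (rounded).
#' @examples
#' fixation_rate(1134, span = 62)$reported  # 18
#' fixation_rate(714, 218, 7)$reported      # 71
#' @export
fixation_rate <- function(births, deaths = 0, span, digits = 0) {
  if (span <= 0) stop("span must be > 0")
  if (deaths < 0 || births < deaths) stop("need births >= deaths >= 0")
  rate <- (births - deaths) / span
  list(births = births, deaths = deaths, span = span, rate = rate,
       reported = round_half_up(rate, digits))
}

#' Proportion as a percentage, with reporting precision
#'
#' @param count Numerator count.
#' @param total Denominator count (> 0).
#' @param digits Decimal places for the reported percentage.
#' @return list with `raw` (percent) and `reported` (rounded percent).
#' @examples
#' proportion_percent(1134, 13955, 1)$reported  # 8.1
#' @export
proportion_percent <- function(count, total, digits = 1) {
  if (total <= 0) stop("total must be > 0")
  pct <- 100 * count / total
  list(raw = pct, reported = round_half_up(pct, digits))
}

#' Gene counts per branch
#'
#' @param ages data.frame as from [read_age_table()].
#' @param biotype Optional biotype filter (`"protein_coding"` or
#'   `"ncRNA"`).
#' @return Named integer vector over all nine branches (zero-filled).
#' @export
branch_counts <- function(ages, biotype = NULL) {
  if (!is.null(biotype)) ages <- ages[ages$biotype == biotype, , drop = FALSE]
  tab <- table(factor(as.character(ages$branch), levels = branch_labels()))
  setNames(as.integer(tab), names(tab))
}

#' Young-gene proportions by chromosome class
#'
#' Compares the proportion of young genes (br1..br6) between chromosome
#' classes (typically sex chromosomes vs autosomes) with a 2x2 chi-squared
#' test (young vs not-young x class).
#'
#' @param ages data.frame as from [read_age_table()].
#' @param chromosome_class Named character vector mapping each chromosome to
#'   a class; every chromosome present in `ages` must be mapped.
#' @return list with `proportions` (percent young per class), `table`
#'   (2x2 counts), `statistic`, `p_value`.
#' @export
chromosome_class_test <- function(ages, chromosome_class) {
  cls <- chromosome_class[ages$chromosome]
  if (anyNA(cls)) {
    stop("unmapped chromosome(s): ",
         paste(unique(ages$chromosome[is.na(cls)]), collapse = ", "))
  }
  if (length(unique(cls)) < 2) {
    stop("need at least two chromosome classes with genes")
  }
  young <- branch_to_age_class(ages$branch) == "young"
  tab <- table(class = cls, young = factor(young, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0)) stop("chromosome class with zero genes")
  prop <- 100 * tab[, "TRUE"] / rowSums(tab)
  if (all(abs(prop - prop[1]) < 1e-12)) {
    # identical proportions: chi-squared statistic 0 by definition
    return(list(proportions = prop, table = tab, statistic = 0, p_value = 1))
  }
  ct <- suppressWarnings(chisq.test(tab))
  list(proportions = prop, table = tab,
       statistic = unname(ct$statistic), p_value = ct$p.value)
}
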