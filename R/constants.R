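# Shared vocabularies: branch labels, age classes, compartments, branch spans.

#' Ordered branch labels of the focal-lineage phylogeny
#'
#' Nine origination strata ordered from the oldest (`br-2`) to the
#' species-specific youngest (`br6`). `br-2` is a cap: genes present in the
#' most distant outgroup clade are at least that old.
#'
#' @return Character vector of the nine branch labels, oldest first.
#' @export
branch_labels <- function() {
  c("br-2", "br-1", "br0", "br1", "br2", "br3", "br4", "br5", "br6")
}

#' Age class labels
#'
#' The four-class collapse of the branch scale: `oldest` = br-2,
#' `older` = br-1, `old` = br0 (the pre-subgenus-split common ancestor),
#' `young` = br1..br6.
#'
#' @return Character vector `c("oldest", "older", "old", "young")`.
#' @export
age_classes <- function() {
  c("oldest", "older", "old", "young")
}

#' Map branch labels to age classes
#'
#' @param branch Character vector of branch labels (see [branch_labels()]).
#' @return Factor of age classes with levels `oldest < older < old < young`.
#' @examples
#' branch_to_age_class(c("br-2", "br0", "br4"))
#' @export
branch_to_age_class <- function(branch) {
  branch <- as.character(branch)
  bad <- setdiff(unique(branch), branch_labels())
  if (length(bad) > 0) {
    stop("unknown branch label(s): ", paste(bad, collapse = ", "))
  }
  cls <- ifelse(branch == "br-2", "oldest",
         ifelse(branch == "br-1", "older",
         ifelse(branch == "br0", "old", "young")))
  factor(cls, levels = age_classes())
}

#' Index of a branch label on the ordered scale
#'
#' @param branch Character vector of branch labels.
#' @return Integer vector; 1 = `br-2` (oldest) .. 9 = `br6` (youngest).
#' @export
branch_index <- function(branch) {
  idx <- match(as.character(branch), branch_labels())
  if (anyNA(idx)) {
    stop("unknown branch label(s): ",
         paste(unique(branch[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Canonical subcellular compartment vocabulary
#'
#' The nine major compartments retained for analysis. A plant-specific
#' `Plastid` column, when present in a prediction table, is dropped on read.
#'
#' @return Character vector of the nine compartment names.
#' @export
compartments <- function() {
  c("Cytoplasm", "Nucleus", "Extracellular", "Cell_membrane",
    "Mitochondrion", "Endoplasmic_reticulum", "Lysosome_Vacuole",
    "Golgi_apparatus", "Peroxisome")
}

#' Three-level grouping of compartments
#'
#' Collapses the nine compartments to `extracellular` (Extracellular),
#' `cell_membrane` (Cell_membrane) and `intracellular` (the other seven).
#'
#' @param compartment Character vector of compartment names.
#' @return Character vector of level-3 group names.
#' @export
compartment_level3 <- function(compartment) {
  compartment <- as.character(compartment)
  bad <- setdiff(unique(compartment), compartments())
  if (length(bad) > 0) {
    stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  }
  ifelse(compartment == "Extracellular", "extracellular",
  ifelse(compartment == "Cell_membrane", "cell_membrane", "intracellular"))
}

#' Default branch time spans
#'
#' Durations in million years for each branch. The young branches (br1..br6)
#' total 62 MY with br6 = 5 MY; br0 spans 7 MY (69 to 62 MY). These follow
#' the divergence-time calibration of the study phylogeny; they are
#' configuration, not constants, and any named numeric vector over
#' [branch_labels()] may be supplied where spans are needed.
#'
#' @return Named numeric vector of spans (MY) per branch label.
#' @export
default_branch_spans <- function() {
  c("br-2" = 50, "br-1" = 31, "br0" = 7,
    "br1" = 20, "br2" = 12, "br3" = 10, "br4" = 8, "br5" = 7, "br6" = 5)
}

# Round half away from zero at d digits; base round() is banker's rounding
# and would turn 0.5-boundary rates the wrong way for reported values.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
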