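# STRING-style link ingestion, compartment-resolved interaction density,
# and the within/between-compartment (WC/BC) sampling simulation.

#' Load a STRING-style physical-links file
#'
#' Whitespace-separated three-column file (protein, protein, combined
#' score), possibly listing both orientations of each edge. Edges with
#' score strictly greater than `cutoff` are kept; reversed duplicates are
#' merged and self-loops dropped (counts reported).
#'
#' @param path Path to the links file (a header line starting with
#'   `protein` is tolerated).
#' @param cutoff Score cutoff (default 700, strict inequality).
#' @return data.frame with columns `protein_a`, `protein_b` (each unordered
#'   pair once, `protein_a < protein_b`), `score`; attributes
#'   `n_self_loops` and `n_below_cutoff` carry the attrition counts.
#' @export
load_links <- function(path, cutoff = 700) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("protein_a", "protein_b", "score"),
                          colClasses = c("character", "character",
                                         "character"))
  if (nrow(df) > 0 && tolower(df$protein_a[1]) %in% c("protein1", "protein")) {
    df <- df[-1, , drop = FALSE]
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    stop("non-numeric score at line ", which(is.na(score))[1])
  }
  df$score <- score
  n_below <- sum(df$score <= cutoff)
  df <- df[df$score > cutoff, , drop = FALSE]
  self <- df$protein_a == df$protein_b
  n_self <- sum(self)
  df <- df[!self, , drop = FALSE]
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(protein_a = a[keep], protein_b = b[keep],
                    score = df$score[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- n_self
  attr(out, "n_below_cutoff") <- n_below
  out
}

#' Write a STRING-style links file (both orientations)
#'
#' @param edges data.frame with `protein_a`, `protein_b`, `score`.
#' @param path Output path.
#' @export
write_links <- function(edges, path) {
  both <- rbind(
    data.frame(a = edges$protein_a, b = edges$protein_b, s = edges$score),
    data.frame(a = edges$protein_b, b = edges$protein_a, s = edges$score))
  writeLines(c("protein1 protein2 combined_score",
               paste(both$a, both$b, both$s)), path)
  invisible(path)
}

# Restrict an edge table to nodes with >= 1 called compartment; returns the
# edge table plus integer-coded compartment sets.
.edge_compartments <- function(edges, called) {
  known <- unique(c(edges$protein_a, edges$protein_b))
  missing <- setdiff(known, names(called))
  if (length(missing) > 0) {
    stop("edges reference proteins without localization calls: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  }
  called
}

#' Compartment-resolved interaction density matrix
#'
#' A 9x9 symmetric matrix of average interactions per gene. The diagonal
#' cell (i, i) counts edges whose endpoints both carry compartment i,
#' divided by the number of genes carrying i. The off-diagonal cell (i, j)
#' counts edges with one endpoint carrying i and the other carrying j whose
#' compartment sets do not intersect (pure between-compartment edges),
#' divided by the number of genes carrying i or j (union denominator, so
#' diagonal and off-diagonal cells share a scale). Multi-localized proteins
#' contribute to every compartment they carry; set
#' `single_localized = TRUE` to restrict to unambiguous proteins.
#'
#' @param edges data.frame from [load_links()].
#' @param called Named list of called-compartment vectors per protein.
#' @param protein_to_gene Optional named character vector mapping protein to
#'   gene id (defaults to identity, one protein per gene).
#' @param single_localized Drop proteins with more than one compartment.
#' @return list with `matrix` (9x9 numeric, NA rows/columns flagged for
#'   compartments with zero genes) and `gene_counts` per compartment.
#' @export
density_matrix <- function(edges, called, protein_to_gene = NULL,
                           single_localized = FALSE) {
  called <- .edge_compartments(edges, called)
  if (single_localized) called <- called[lengths(called) == 1]
  if (is.null(protein_to_gene)) {
    protein_to_gene <- setNames(names(called), names(called))
  }
  cps <- compartments()
  genes_by_comp <- lapply(cps, function(cc) {
    unique(protein_to_gene[names(called)[vapply(called, function(s)
      cc %in% s, logical(1))]])
  })
  names(genes_by_comp) <- cps
  gene_counts <- lengths(genes_by_comp)

  keep <- edges$protein_a %in% names(called) &
    edges$protein_b %in% names(called)
  edges <- edges[keep, , drop = FALSE]
  mat <- matrix(0, 9, 9, dimnames = list(cps, cps))
  ia <- called[edges$protein_a]
  ib <- called[edges$protein_b]
  for (e in seq_len(nrow(edges))) {
    sa <- ia[[e]]
    sb <- ib[[e]]
    shared <- intersect(sa, sb)
    if (length(shared) > 0) {
      for (cc in shared) mat[cc, cc] <- mat[cc, cc] + 1
    } else {
      for (x in sa) for (y in sb) {
        mat[x, y] <- mat[x, y] + 1
        mat[y, x] <- mat[y, x] + 1
      }
    }
  }
  dens <- mat
  for (i in cps) {
    for (j in cps) {
      denom <- if (i == j) gene_counts[i] else
        length(union(genes_by_comp[[i]], genes_by_comp[[j]]))
      dens[i, j] <- if (denom > 0) mat[i, j] / denom else NA_real_
    }
  }
  list(matrix = dens, gene_counts = gene_counts)
}

#' Within- vs between-compartment interaction simulation
#'
#' Repeatedly samples `sample_size` interaction pairs without replacement
#' from the graph, splits them into within-compartment (endpoint call sets
#' intersect) and between-compartment edges, and computes per-simulation
#' per-gene interaction frequencies (edges in the group divided by distinct
#' genes touched by the group). The two frequency collections are compared
#' with a two-sided Mann-Whitney test.
#'
#' @param edges data.frame from [load_links()].
#' @param called Named list of called-compartment vectors per protein.
#' @param n_sims Number of simulations (default 50).
#' @param sample_size Pairs per simulation (default 50000; reduced with a
#'   warning when the graph has fewer edges).
#' @param seed Optional integer seed.
#' @param protein_to_gene Optional protein-to-gene map (defaults to
#'   identity).
#' @return list with `per_sim` (data.frame: sim, n_wc, n_bc, wc_share =
#'   n_wc / sample_size, wc_freq, bc_freq), `p_value`, `sample_size`.
#' @export
wc_bc_simulation <- function(edges, called, n_sims = 50,
                             sample_size = 50000, seed = NULL,
                             protein_to_gene = NULL) {
  if (nrow(edges) == 0) stop("empty interaction graph")
  called <- .edge_compartments(edges, called)
  if (is.null(protein_to_gene)) {
    protein_to_gene <- setNames(names(called), names(called))
  }
  if (!is.null(seed)) set.seed(seed)
  if (sample_size > nrow(edges)) {
    warning("sample_size reduced to the number of edges (",
            nrow(edges), ")")
    sample_size <- nrow(edges)
  }
  wc_edge <- mapply(function(a, b) {
    length(intersect(called[[a]], called[[b]])) > 0
  }, edges$protein_a, edges$protein_b, USE.NAMES = FALSE)
  ga <- protein_to_gene[edges$protein_a]
  gb <- protein_to_gene[edges$protein_b]
  per_sim <- data.frame(sim = seq_len(n_sims), n_wc = NA_integer_,
                        n_bc = NA_integer_, wc_share = NA_real_,
                        wc_freq = NA_real_, bc_freq = NA_real_)
  for (s in seq_len(n_sims)) {
    idx <- sample.int(nrow(edges), sample_size, replace = FALSE)
    wc <- wc_edge[idx]
    n_wc <- sum(wc)
    n_bc <- sample_size - n_wc
    wc_genes <- length(unique(c(ga[idx][wc], gb[idx][wc])))
    bc_genes <- length(unique(c(ga[idx][!wc], gb[idx][!wc])))
    per_sim$n_wc[s] <- n_wc
    per_sim$n_bc[s] <- n_bc
    per_sim$wc_share[s] <- n_wc / sample_size
    per_sim$wc_freq[s] <- if (wc_genes > 0) n_wc / wc_genes else 0
    per_sim$bc_freq[s] <- if (bc_genes > 0) n_bc / bc_genes else 0
  }
  p <- suppressWarnings(
    wilcox.test(per_sim$wc_freq, per_sim$bc_freq)$p.value)
  list(per_sim = per_sim, p_value = p, sample_size = sample_size)
}
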