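# Seeded generator for every input class the pipeline consumes, with ground
# truth retained for recovery tests. Each generator draws from its own
# pseudo-random substream derived from the master seed, so changing the
# number of draws in one generator never perturbs another's output.

.substream <- function(seed, k) {
  if (is.null(seed)) return(invisible(NULL))
  set.seed((as.integer(seed) + 77003L * k) %% 2147483L + 1L)
}

#' Simulation parameters
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions: branch birth weights proportional to the reported
#' per-branch gene counts, an extracellular skew for young genes, broader
#' localization for deep-branch genes, a 5x within-compartment edge
#' preference, a 2x co-function boost for non-cap branches, and a 3x
#' elevated substitution rate for extracellular proteins.
#'
#' @param n_genes Number of genes (one protein per gene; ids shared).
#' @param branch_birth_weights Named non-negative weights per branch label.
#' @param outgroup_loss_prob Probability a pre-loss presence is flipped to
#'   absent; scalar or named per clade id.
#' @param secondary_loss_prob Loss probability for the secondary
#'   older-level outgroup used by the loss correction.
#' @param clades A [clade_map()] (default [default_clade_map()]).
#' @param compartment_preference 4x9 row-stochastic matrix (rows =
#'   [age_classes()], columns = [compartments()]): primary-compartment
#'   distribution per age class.
#' @param multi_label_rate Probability an additional compartment is added
#'   to a protein's set (applied repeatedly, so call-set breadth is
#'   geometric); scalar or named per age class.
#' @param n_edges Number of distinct interaction edges to sample.
#' @param within_edge_preference Odds multiplier for sampling an edge
#'   between proteins sharing a compartment (`Inf` = within only).
#' @param n_pathways Number of pathway ids.
#' @param cofunction_boost Target multiplier on the within-branch
#'   co-function probability for branches younger than the cap branch
#'   (1 = no structure).
#' @param substitution_rate_by_compartment Named per-site substitution
#'   probability per compartment (family members diverge from their family
#'   ancestor at this rate).
#' @param n_families_per_compartment Upper bound on sequence families
#'   formed per compartment for the divergence analysis.
#' @param family_sizes Possible family sizes (sampled uniformly).
#' @param sequence_length_range Min/max ancestor sequence length.
#' @param n_paralog_pairs Number of paralogous gene pairs.
#' @param paralog_pattern_mix Named probabilities over the change patterns
#'   `K`, `SE`, `S`, `E`, `KE`.
#' @param paralog_sub_rate Per-site substitution rate between K-pair
#'   sequences.
#' @param paralog_nonk_rate_mult Rate multiplier for non-K pairs.
#' @param paralog_nonk_nterm_frac Fraction of non-K substitutions placed in
#'   the N-terminal third.
#' @param ncrna_fraction Fraction of genes emitted as ncRNA biotype.
#' @param sex_young_boost Multiplier on sex-chromosome weights for young
#'   genes (emulates the sex-chromosome excess of new genes).
#' @param seed Master integer seed; fully determines every output.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(
    n_genes = 4000,
    branch_birth_weights = c("br-2" = 11.0, "br-1" = 1.1, "br0" = 0.71,
                             "br1" = 0.20, "br2" = 0.28, "br3" = 0.24,
                             "br4" = 0.33, "br5" = 0.05, "br6" = 0.05),
    outgroup_loss_prob = 0,
    secondary_loss_prob = 0,
    clades = default_clade_map(),
    compartment_preference = NULL,
    multi_label_rate = c(oldest = 0.5, older = 0.4, old = 0.3,
                         young = 0.15),
    n_edges = 10000,
    within_edge_preference = 5,
    n_pathways = 50,
    cofunction_boost = 2,
    substitution_rate_by_compartment = NULL,
    n_families_per_compartment = 60,
    family_sizes = c(2, 3),
    sequence_length_range = c(70, 110),
    n_paralog_pairs = 200,
    paralog_pattern_mix = c(K = 0.667, SE = 0.053, S = 0.10, E = 0.06,
                            KE = 0.12),
    paralog_sub_rate = 0.03,
    paralog_nonk_rate_mult = 3,
    paralog_nonk_nterm_frac = 0.7,
    ncrna_fraction = 0.15,
    sex_young_boost = 1.5,
    seed = 1L) {
  if (is.null(compartment_preference)) {
    compartment_preference <- default_compartment_preference()
  }
  stopifnot(nrow(compartment_preference) == 4,
            ncol(compartment_preference) == 9)
  if (any(abs(rowSums(compartment_preference) - 1) > 1e-8)) {
    stop("compartment_preference rows must sum to 1")
  }
  stopifnot(all(branch_labels() %in% names(branch_birth_weights)))
  if (any(branch_birth_weights < 0) || sum(branch_birth_weights) <= 0) {
    stop("branch_birth_weights must be non-negative with positive sum")
  }
  if (length(multi_label_rate) == 1) {
    multi_label_rate <- setNames(rep(multi_label_rate, 4), age_classes())
  }
  probs <- c(outgroup_loss_prob, secondary_loss_prob, multi_label_rate,
             paralog_sub_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (is.null(substitution_rate_by_compartment)) {
    substitution_rate_by_compartment <-
      setNames(rep(0.05, 9), compartments())
    substitution_rate_by_compartment["Extracellular"] <- 0.15
  }
  if (abs(sum(paralog_pattern_mix) - 1) > 1e-8) {
    stop("paralog_pattern_mix must sum to 1")
  }
  p <- list(n_genes = n_genes,
            branch_birth_weights = branch_birth_weights[branch_labels()],
            outgroup_loss_prob = outgroup_loss_prob,
            secondary_loss_prob = secondary_loss_prob,
            clades = clades,
            compartment_preference = compartment_preference,
            multi_label_rate = multi_label_rate,
            n_edges = n_edges,
            within_edge_preference = within_edge_preference,
            n_pathways = n_pathways,
            cofunction_boost = cofunction_boost,
            substitution_rate_by_compartment =
              substitution_rate_by_compartment,
            n_families_per_compartment = n_families_per_compartment,
            family_sizes = family_sizes,
            sequence_length_range = sequence_length_range,
            n_paralog_pairs = n_paralog_pairs,
            paralog_pattern_mix = paralog_pattern_mix,
            paralog_sub_rate = paralog_sub_rate,
            paralog_nonk_rate_mult = paralog_nonk_rate_mult,
            paralog_nonk_nterm_frac = paralog_nonk_nterm_frac,
            ncrna_fraction = ncrna_fraction,
            sex_young_boost = sex_young_boost,
            seed = seed)
  class(p) <- "simulation_params"
  p
}

#' Default per-age-class compartment preference
#'
#' Row-stochastic 4x9 matrix encoding the structure the analysis expects to
#' detect: young genes skewed toward the extracellular space, deep-branch
#' genes toward intracellular compartments.
#'
#' @return Numeric matrix, rows [age_classes()], columns [compartments()].
#' @export
default_compartment_preference <- function() {
  m <- rbind(
    oldest = c(0.25, 0.30, 0.04, 0.08, 0.15, 0.07, 0.04, 0.04, 0.03),
    older  = c(0.24, 0.26, 0.08, 0.08, 0.14, 0.08, 0.04, 0.05, 0.03),
    old    = c(0.20, 0.20, 0.20, 0.10, 0.10, 0.08, 0.04, 0.05, 0.03),
    young  = c(0.15, 0.14, 0.35, 0.10, 0.08, 0.07, 0.04, 0.04, 0.03))
  colnames(m) <- compartments()
  m
}

#' Uniform compartment preference (null structure)
#'
#' All age classes share the same compartment distribution, so every
#' enrichment excess has expectation zero.
#'
#' @param weights Optional common distribution over the nine compartments
#'   (defaults to uniform 1/9).
#' @return Row-stochastic 4x9 matrix.
#' @export
uniform_compartment_preference <- function(weights = NULL) {
  if (is.null(weights)) weights <- rep(1 / 9, 9)
  weights <- weights / sum(weights)
  m <- matrix(rep(weights, 4), nrow = 4, byrow = TRUE,
              dimnames = list(age_classes(), compartments()))
  m
}

#' Generate gene histories and the ortholog presence matrix
#'
#' Each gene is born on a branch drawn from `branch_birth_weights`; its
#' pre-loss presence covers exactly the clades that diverged after its
#' birth, and each presence is independently flipped to absent with the
#' outgroup loss probability. A secondary outgroup at the `br-1` level
#' (used by the loss correction) is emitted alongside, with its own loss
#' probability. Chromosomes and biotypes are assigned here too.
#'
#' @param params A [simulation_params()] object.
#' @return list with `presence` (logical gene x clade matrix, post-loss),
#'   `secondary_presence` (named logical vector), `truth` (data.frame:
#'   gene_id, true_branch, biotype, chromosome), `loss_events` (logical
#'   matrix of flipped presences), `clades`.
#' @export
gen_gene_history <- function(params) {
  .substream(params$seed, 1L)
  n <- params$n_genes
  clades <- params$clades
  if (n == 0) {
    empty <- matrix(logical(), 0, nrow(clades),
                    dimnames = list(NULL, clades$clade_id))
    return(list(presence = empty, secondary_presence = logical(),
                truth = data.frame(gene_id = character(),
                                   true_branch = character(),
                                   biotype = character(),
                                   chromosome = character()),
                loss_events = empty, clades = clades))
  }
  gene_id <- sprintf("g%05d", seq_len(n))
  w <- params$branch_birth_weights
  true_branch <- sample(branch_labels(), n, replace = TRUE,
                        prob = w / sum(w))
  biotype <- ifelse(runif(n) < params$ncrna_fraction, "ncRNA",
                    "protein_coding")
  chroms <- c(X = 0.18, Y = 0.01, `2L` = 0.20, `2R` = 0.20, `3L` = 0.20,
              `3R` = 0.19, `4` = 0.02)
  young <- branch_to_age_class(true_branch) == "young"
  chromosome <- character(n)
  w_old <- chroms
  w_young <- chroms
  w_young[c("X", "Y")] <- w_young[c("X", "Y")] * params$sex_young_boost
  chromosome[!young] <- sample(names(chroms), sum(!young), replace = TRUE,
                               prob = w_old)
  chromosome[young] <- sample(names(chroms), sum(young), replace = TRUE,
                              prob = w_young / sum(w_young))

  clade_idx <- branch_index(clades$implied_branch)
  born_idx <- branch_index(true_branch)
  pre_loss <- outer(born_idx, clade_idx, "<=")
  dimnames(pre_loss) <- list(gene_id, clades$clade_id)
  loss_p <- params$outgroup_loss_prob
  if (length(loss_p) == 1) {
    loss_p <- setNames(rep(loss_p, nrow(clades)), clades$clade_id)
  }
  flips <- matrix(runif(length(pre_loss)), nrow = n) <
    matrix(loss_p[colnames(pre_loss)], nrow = n, ncol = nrow(clades),
           byrow = TRUE)
  loss_events <- pre_loss & flips
  presence <- pre_loss & !flips

  sec_pre <- born_idx <= 2L  # present in an older-level (br-1) outgroup
  sec_flip <- runif(n) < params$secondary_loss_prob
  secondary_presence <- setNames(sec_pre & !sec_flip, gene_id)

  truth <- data.frame(gene_id = gene_id, true_branch = true_branch,
                      biotype = biotype, chromosome = chromosome,
                      stringsAsFactors = FALSE)
  list(presence = presence, secondary_presence = secondary_presence,
       truth = truth, loss_events = loss_events, clades = clades)
}

#' Generate a localization probability table
#'
#' Each protein draws a primary compartment from its age class's
#' preference row; further compartments are appended while a coin with the
#' age class's `multi_label_rate` keeps coming up heads. Compartments in
#' the assigned set get probabilities drawn strictly above 0.5, all others
#' strictly below, so the 0.5 calling rule is unambiguous on synthetic
#' data.
#'
#' @param history Output of [gen_gene_history()].
#' @param params A [simulation_params()] object.
#' @return list with `localization` (data.frame: protein_id plus the nine
#'   probability columns) and `called` (named list of true compartment
#'   sets).
#' @export
gen_localizations <- function(history, params) {
  .substream(params$seed, 2L)
  truth <- history$truth
  n <- nrow(truth)
  cls <- as.character(branch_to_age_class(truth$true_branch))
  pref <- params$compartment_preference
  rate <- params$multi_label_rate
  cps <- compartments()
  called <- vector("list", n)
  probs <- matrix(0, n, 9, dimnames = list(truth$gene_id, cps))
  for (i in seq_len(n)) {
    set <- sample(cps, 1, prob = pref[cls[i], ])
    while (length(set) < 9 && runif(1) < rate[cls[i]]) {
      set <- c(set, sample(setdiff(cps, set), 1))
    }
    called[[i]] <- set
    p <- runif(9, 0, 0.499)
    p[match(set, cps)] <- runif(length(set), 0.501, 1)
    probs[i, ] <- round(p, 4)
  }
  names(called) <- truth$gene_id
  loc <- data.frame(protein_id = truth$gene_id, probs, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(loc) <- NULL
  list(localization = loc, called = called)
}

#' Generate a STRING-style physical-link table
#'
#' Distinct unordered protein pairs are sampled with acceptance-rejection:
#' pairs sharing a compartment are accepted `within_edge_preference` times
#' as often as pairs that do not. Scores are uniform integers in
#' [701, 999] so every edge survives the default score filter.
#'
#' @param called Named list of compartment sets per protein.
#' @param params A [simulation_params()] object.
#' @return data.frame with `protein_a`, `protein_b`, `score` (each edge
#'   once; [write_links()] emits both orientations).
#' @export
gen_ppi <- function(called, params) {
  .substream(params$seed, 3L)
  ids <- names(called)
  n <- length(ids)
  n_edges <- params$n_edges
  if (n_edges == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  max_pairs <- n * (n - 1) / 2
  if (n_edges > max_pairs) {
    stop("n_edges (", n_edges, ") exceeds the number of distinct pairs (",
         max_pairs, ")")
  }
  pref <- params$within_edge_preference
  comp_code <- lapply(called, function(s) match(s, compartments()))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  a_out <- character(n_edges)
  b_out <- character(n_edges)
  got <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n_edges
  while (got < n_edges) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("edge sampling did not converge; within_edge_preference ",
           "may be infeasible for this compartment structure")
    }
    ij <- sample.int(n, 2)
    i <- min(ij); j <- max(ij)
    within <- length(intersect(comp_code[[i]], comp_code[[j]])) > 0
    if (is.infinite(pref)) {
      if (!within) next
    } else if (!within && runif(1) > 1 / max(pref, 1)) {
      next
    } else if (within && pref < 1 && runif(1) > pref) {
      next
    }
    key <- paste0(i, "_", j)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1L
    a_out[got] <- ids[i]
    b_out[got] <- ids[j]
  }
  data.frame(protein_a = a_out, protein_b = b_out,
             score = sample.int(299, n_edges, replace = TRUE) + 700,
             stringsAsFactors = FALSE)
}

#' Generate pathway annotations
#'
#' Every branch except the cap branch (`br-2`) has a preferred pathway its
#' proteins adopt with probability `q = sqrt((boost - 1) / n_pathways)`;
#' otherwise a pathway is drawn uniformly. The within-branch co-function
#' probability is then about `boost / n_pathways`, i.e. `boost` times the
#' uniform baseline, while cap-branch proteins stay at baseline.
#'
#' @param history Output of [gen_gene_history()].
#' @param params A [simulation_params()] object.
#' @return Named list mapping protein id to a pathway-id character vector
#'   (one pathway per protein).
#' @export
gen_pathways <- function(history, params) {
  .substream(params$seed, 4L)
  if (params$n_pathways < 1) stop("n_pathways must be >= 1")
  k <- params$n_pathways
  boost <- params$cofunction_boost
  q <- min(1, sqrt(max(boost - 1, 0) / k))
  pw_ids <- sprintf("path%03d", seq_len(k))
  br <- history$truth$true_branch
  pref_pw <- setNames(sample(pw_ids, length(branch_labels()),
                             replace = TRUE), branch_labels())
  n <- nrow(history$truth)
  assigned <- character(n)
  uniform_draw <- sample(pw_ids, n, replace = TRUE)
  adopt <- runif(n) < q & br != "br-2"
  assigned[!adopt] <- uniform_draw[!adopt]
  assigned[adopt] <- pref_pw[br[adopt]]
  setNames(lapply(assigned, identity), history$truth$gene_id)
}

# random amino-acid sequence over the 20 standard residues
.random_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# substitute residues at the given rate; optionally concentrate a fraction
# of the substituted positions in the N-terminal third
.mutate_seq <- function(seq, rate, nterm_frac = NA) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  len <- length(chars)
  n_sub <- rbinom(1, len, rate)
  if (n_sub == 0) return(seq)
  if (is.na(nterm_frac)) {
    pos <- sample.int(len, n_sub)
  } else {
    third <- max(1, floor(len / 3))
    n_nt <- min(rbinom(1, n_sub, nterm_frac), third)
    pos_nt <- sample.int(third, n_nt)
    rest <- setdiff(seq_len(len), seq_len(third))
    pos_rest <- sample(rest, min(n_sub - n_nt, length(rest)))
    pos <- c(pos_nt, pos_rest)
  }
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate paralog pairs and protein sequences
#'
#' Two sequence universes are produced. (1) Sequence families for the
#' divergence analysis: single-localized genes are grouped by compartment
#' and age class into families; members diverge from a common ancestor at
#' the compartment's substitution rate, so compartments with elevated
#' rates yield clusters with elevated D. (2) Paralog pairs among the
#' remaining genes: each pair is designated a change pattern from
#' `paralog_pattern_mix`; offspring localization sets are constructed to
#' realize the pattern (overriding the generated localization rows), and
#' offspring sequences derive from the parent by per-site substitution —
#' uniform in position for K pairs, concentrated in the N-terminal third
#' and at an elevated rate for non-K pairs.
#'
#' @param history Output of [gen_gene_history()].
#' @param called Named list of compartment sets (from
#'   [gen_localizations()]).
#' @param params A [simulation_params()] object.
#' @return list with `pairs` (data.frame: gene_id, paralog_id,
#'   true_pattern, parent, offspring), `sequences` (named character
#'   vector), `localization_overrides` (named list of new compartment sets
#'   for offspring/parent proteins), `families` (data.frame: gene_id,
#'   family_id, compartment).
#' @export
gen_paralogs_and_sequences <- function(history, called, params) {
  .substream(params$seed, 5L)
  truth <- history$truth
  cls <- as.character(branch_to_age_class(truth$true_branch))
  len_rng <- params$sequence_length_range
  rates <- params$substitution_rate_by_compartment

  # --- sequence families ---------------------------------------------------
  single <- names(called)[lengths(called) == 1]
  comp1 <- vapply(called[single], `[`, character(1), 1)
  fam_rows <- list()
  seqs <- character(0)
  fam_counter <- 0L
  for (cc in compartments()) {
    pool_all <- single[comp1 == cc]
    n_fam_c <- 0L
    for (ac in age_classes()) {
      if (n_fam_c >= params$n_families_per_compartment) break
      pool <- pool_all[cls[match(pool_all, truth$gene_id)] == ac]
      if (length(pool) < 2) next
      pool <- sample(pool)
      while (length(pool) >= 2 &&
             n_fam_c < params$n_families_per_compartment) {
        size <- sample(params$family_sizes, 1)
        size <- min(size, length(pool))
        if (size < 2) break
        members <- pool[seq_len(size)]
        pool <- pool[-seq_len(size)]
        fam_counter <- fam_counter + 1L
        n_fam_c <- n_fam_c + 1L
        fid <- sprintf("fam%04d", fam_counter)
        anc <- .random_seq(sample(len_rng[1]:len_rng[2], 1))
        for (m in members) {
          seqs[m] <- .mutate_seq(anc, rates[cc])
        }
        fam_rows[[length(fam_rows) + 1L]] <-
          data.frame(gene_id = members, family_id = fid, compartment = cc,
                     stringsAsFactors = FALSE)
      }
    }
  }
  families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
    data.frame(gene_id = character(), family_id = character(),
               compartment = character(), stringsAsFactors = FALSE)

  # --- paralog pairs -------------------------------------------------------
  free <- setdiff(truth$gene_id, families$gene_id)
  free_branch <- branch_index(truth$true_branch[match(free, truth$gene_id)])
  patterns <- names(params$paralog_pattern_mix)
  overrides <- list()
  pair_rows <- list()
  n_target <- params$n_paralog_pairs
  used <- character(0)
  attempts <- 0L
  while (length(pair_rows) < n_target && attempts < 50L * n_target) {
    attempts <- attempts + 1L
    avail <- setdiff(free, used)
    if (length(avail) < 2) break
    cand <- sample(avail, 2)
    bi <- free_branch[match(cand, free)]
    if (bi[1] == bi[2]) next
    parent <- cand[which.min(bi)]
    offspring <- cand[which.max(bi)]
    pat <- sample(patterns, 1, prob = params$paralog_pattern_mix)

    p_set <- called[[parent]]
    cps <- compartments()
    # make the parent set compatible with the designated pattern
    if (pat %in% c("S", "SE") && length(p_set) < 2) {
      p_set <- c(p_set, sample(setdiff(cps, p_set), 1))
      overrides[[parent]] <- p_set
    }
    if (pat == "KE" && length(p_set) >= 9) {
      p_set <- p_set[-1]
      overrides[[parent]] <- p_set
    }
    o_set <- switch(pat,
      K = p_set,
      KE = c(p_set, sample(setdiff(cps, p_set), 1)),
      S = p_set[seq_len(length(p_set) - 1)],
      E = sample(setdiff(cps, p_set),
                 min(max(1, length(p_set)), length(setdiff(cps, p_set)))),
      SE = c(p_set[seq_len(length(p_set) - 1)],
             sample(setdiff(cps, p_set), 1)))
    overrides[[offspring]] <- o_set

    p_seq <- if (!is.na(seqs[parent])) seqs[parent] else
      .random_seq(sample(len_rng[1]:len_rng[2], 1))
    seqs[parent] <- p_seq
    if (pat == "K") {
      seqs[offspring] <- .mutate_seq(p_seq, params$paralog_sub_rate)
    } else {
      seqs[offspring] <- .mutate_seq(
        p_seq,
        min(1, params$paralog_sub_rate * params$paralog_nonk_rate_mult),
        params$paralog_nonk_nterm_frac)
    }
    used <- c(used, cand)
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(gene_id = parent, paralog_id = offspring,
                 parent = parent, offspring = offspring,
                 true_pattern = pat, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(gene_id = character(), paralog_id = character(),
               parent = character(), offspring = character(),
               true_pattern = character(), stringsAsFactors = FALSE)
  seqs <- seqs[!is.na(seqs)]
  list(pairs = pairs, sequences = seqs,
       localization_overrides = overrides, families = families)
}

#' Generate a toy transcript annotation (GTF)
#'
#' One gene record per gene with one or two transcripts of one to three
#' exons each; the longest transcript is the representative whose protein
#' the other tables describe. Coordinates are synthetic and non-overlapping
#' within a chromosome.
#'
#' @param history Output of [gen_gene_history()].
#' @param params A [simulation_params()] object.
#' @return Character vector of GTF lines.
#' @export
gen_gtf_lines <- function(history, params) {
  .substream(params$seed, 6L)
  truth <- history$truth
  lines <- vector("list", nrow(truth))
  offsets <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    chr <- truth$chromosome[i]
    base <- if (is.null(offsets[[chr]])) 1000L else offsets[[chr]]
    n_tx <- sample(1:2, 1)
    gene_end <- base
    gene_lines <- character(0)
    for (t in seq_len(n_tx)) {
      tx <- paste0(g, ".t", t)
      n_ex <- sample(1:3, 1)
      pos <- base
      for (e in seq_len(n_ex)) {
        w <- sample(100:400, 1)
        attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g, tx)
        gene_lines <- c(gene_lines,
                        paste(chr, "synthetic", "exon", pos, pos + w - 1,
                              ".", "+", ".", attrs, sep = "\t"))
        gene_end <- max(gene_end, pos + w - 1)
        pos <- pos + w + 50L
      }
    }
    lines[[i]] <- gene_lines
    offsets[[chr]] <- gene_end + 5000L
  }
  unlist(lines)
}

#' Run every generator and assemble (or write) a complete dataset
#'
#' Orchestrates the substreamed generators in a fixed order, applies the
#' paralog localization overrides to the probability table, and optionally
#' writes every table in the dialect its reader expects, plus a
#' ground-truth TSV.
#'
#' @param params A [simulation_params()] object.
#' @param dir Optional output directory (created if needed); when NULL the
#'   dataset is only returned in memory.
#' @return list with `presence`, `secondary_presence`, `localization`,
#'   `called` (post-override truth sets), `edges`, `pathways`, `pairs`,
#'   `sequences`, `families`, `truth`, `clades`, `gtf_lines`, and (when
#'   written) `paths`.
#' @export
simulate_dataset <- function(params = simulation_params(), dir = NULL) {
  history <- gen_gene_history(params)
  locs <- gen_localizations(history, params)
  edges <- gen_ppi(locs$called, params)
  pathways <- gen_pathways(history, params)
  para <- gen_paralogs_and_sequences(history, locs$called, params)
  gtf_lines <- gen_gtf_lines(history, params)

  called <- locs$called
  loc <- locs$localization
  cps <- compartments()
  .substream(params$seed, 7L)
  for (pid in names(para$localization_overrides)) {
    set <- para$localization_overrides[[pid]]
    called[[pid]] <- set
    row <- match(pid, loc$protein_id)
    p <- round(runif(9, 0, 0.499), 4)
    p[match(set, cps)] <- round(runif(length(set), 0.501, 1), 4)
    loc[row, cps] <- as.list(p)
  }

  out <- list(presence = history$presence,
              secondary_presence = history$secondary_presence,
              localization = loc, called = called, edges = edges,
              pathways = pathways, pairs = para$pairs,
              sequences = para$sequences, families = para$families,
              truth = history$truth, clades = history$clades,
              gtf_lines = gtf_lines)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      presence = file.path(dir, "presence.tsv"),
      localization = file.path(dir, "localization.csv"),
      links = file.path(dir, "links.txt"),
      pathways = file.path(dir, "pathways.tsv"),
      paralogs = file.path(dir, "paralogs.tsv"),
      fasta = file.path(dir, "proteins.fa"),
      gtf = file.path(dir, "annotation.gtf"),
      truth = file.path(dir, "ground_truth.tsv"))
    write_presence_matrix(out$presence, paths$presence)
    write_localization_table(out$localization, paths$localization)
    write_links(out$edges, paths$links)
    pw_df <- data.frame(protein_id = rep(names(out$pathways),
                                         lengths(out$pathways)),
                        pathway_id = unlist(out$pathways),
                        stringsAsFactors = FALSE)
    write.table(pw_df, paths$pathways, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_paralog_table(out$pairs, paths$paralogs)
    write_fasta(out$sequences, paths$fasta)
    writeLines(out$gtf_lines, paths$gtf)
    tr <- out$truth
    tr$secondary_presence <- out$secondary_presence[tr$gene_id] * 1L
    tr$true_compartments <- vapply(called[tr$gene_id], paste,
                                   character(1), collapse = ";")
    write.table(tr, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}
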