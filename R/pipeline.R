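# Orchestrates simulate -> age -> enrich -> pairs -> diverge -> ppi ->
# paralogs with one configuration, structured logging and a run manifest.

#' Default run configuration
#'
#' All analysis thresholds at their standard values: 0.5 localization
#' probability, score cutoff 700, masked-exon cutoff 0.70, clustering
#' identity 0.5 with word length 3, more than 40 clusters per retained
#' compartment, 100 co-localization iterations, 50 interaction simulations
#' of 50,000 sampled pairs.
#'
#' @param seed Master seed for the stochastic stages.
#' @param outdir Output directory.
#' @param ... Overrides for any configuration entry.
#' @return Named list of configuration values.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("subcellevo_"),
                               ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    localization_threshold = 0.5,
    score_cutoff = 700,
    masked_exon_max = 0.70,
    cluster_identity = 0.5,
    cluster_word_length = 3,
    min_clusters_per_compartment = 40,
    coloc_iterations = 100,
    coloc_strategy = "A",
    wc_bc_sims = 50,
    wc_bc_sample = 50000,
    presence = NULL, localization = NULL, links = NULL, pathways = NULL,
    paralogs = NULL, fasta = NULL, gtf = NULL)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read a flat key/value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(out, keys)
}

.log_line <- function(...) {
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order. With `"simulate"` among the stages a
#' synthetic dataset is generated (and written to `config$outdir`) and
#' used as input; otherwise the configured input paths must exist before
#' any stage runs. A manifest (per-stage row counts, thresholds, seed) is
#' written to the output directory and returned.
#'
#' @param config List from [default_run_config()] (or
#'   [read_run_config()]).
#' @param stages Character subset of `c("simulate", "age", "enrich",
#'   "pairs", "diverge", "ppi", "paralogs")`; default all.
#' @param sim_params Optional [simulation_params()] for the simulate
#'   stage (its seed is forced to `config$seed`).
#' @return list of per-stage results plus `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "age", "enrich", "pairs",
                                    "diverge", "ppi", "paralogs"),
                         sim_params = NULL) {
  known <- c("simulate", "age", "enrich", "pairs", "diverge", "ppi",
             "paralogs")
  unknown <- setdiff(stages, known)
  if (length(unknown) > 0) stop("unknown stage(s): ",
                                paste(unknown, collapse = ", "))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(seed = config$seed, stages = stages,
                   thresholds = config[c("localization_threshold",
                                         "score_cutoff", "masked_exon_max",
                                         "cluster_identity",
                                         "cluster_word_length",
                                         "min_clusters_per_compartment",
                                         "coloc_iterations", "wc_bc_sims",
                                         "wc_bc_sample")],
                   counts = list())

  if ("simulate" %in% stages) {
    if (is.null(sim_params)) sim_params <- simulation_params()
    sim_params$seed <- config$seed
    sim <- simulate_dataset(sim_params, dir = file.path(outdir, "inputs"))
    for (k in names(sim$paths)) config[[k]] <- sim$paths[[k]]
    config$presence <- sim$paths$presence
    res$simulate <- sim
    manifest$counts$simulate <- c(genes = nrow(sim$truth),
                                  edges = nrow(sim$edges),
                                  paralog_pairs = nrow(sim$pairs))
    .log_line("simulate: ", nrow(sim$truth), " genes, ",
              nrow(sim$edges), " edges, ", nrow(sim$pairs),
              " paralog pairs")
  } else {
    needed <- c("presence", "localization")
    if ("pairs" %in% stages) needed <- c(needed, "pathways")
    if ("diverge" %in% stages || "paralogs" %in% stages) {
      needed <- c(needed, "fasta")
    }
    if ("ppi" %in% stages) needed <- c(needed, "links")
    if ("paralogs" %in% stages) needed <- c(needed, "paralogs")
    for (k in unique(needed)) {
      if (is.null(config[[k]]) || !file.exists(config[[k]])) {
        stop("missing input for stage pre-flight: ", k)
      }
    }
  }

  run_any <- any(c("age", "enrich", "pairs", "diverge", "ppi",
                   "paralogs") %in% stages)
  if (run_any) {
    presence <- read_presence_matrix(config$presence)
    ages <- assign_ages(presence, default_clade_map())
  }

  if ("age" %in% stages) {
    age_df <- data.frame(gene_id = names(ages), branch = ages,
                         biotype = "protein_coding", chromosome = "NA",
                         stringsAsFactors = FALSE)
    if (!is.null(res$simulate)) {
      tr <- res$simulate$truth
      age_df$biotype <- tr$biotype[match(age_df$gene_id, tr$gene_id)]
      age_df$chromosome <- tr$chromosome[match(age_df$gene_id, tr$gene_id)]
    }
    age_df$branch <- factor(age_df$branch, levels = branch_labels())
    write_age_table(age_df, file.path(outdir, "gene_ages.tsv"))
    res$age <- age_df
    cnt <- branch_counts(age_df)
    manifest$counts$age <- cnt
    .log_line("age: ", paste(names(cnt), cnt, sep = "=", collapse = " "))
  }

  loc_needed <- any(c("enrich", "pairs", "diverge", "ppi", "paralogs")
                    %in% stages)
  if (loc_needed) {
    loc <- read_localization_table(config$localization)
    called <- localization_calls(loc, config$localization_threshold)
    n_unloc <- sum(lengths(called) == 0)
    .log_line("localization: ", length(called), " proteins, ",
              n_unloc, " unlocalized")
  }

  if ("enrich" %in% stages) {
    shared <- intersect(names(ages), names(called))
    groups <- setNames(as.character(ages[shared]), shared)
    enr <- enrichment(groups, called, level = "compartment")
    enr3 <- enrichment(setNames(as.character(
      branch_to_age_class(ages[shared])), shared), called,
      level = "level3")
    breadth <- breadth_by_age(called,
                              setNames(as.character(
                                branch_to_age_class(ages[shared])), shared))
    write.table(enr$table, file.path(outdir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(breadth, file.path(outdir, "breadth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$enrich <- list(compartment = enr, level3 = enr3, breadth = breadth)
    manifest$counts$enrich <- c(proteins = length(shared),
                                unlocalized = enr$n_unlocalized)
  }

  if ("pairs" %in% stages) {
    shared <- intersect(names(ages), names(called))
    single <- shared[lengths(called[shared]) == 1]
    comp1 <- vapply(called[single], `[`, character(1), 1)
    coloc <- colocalization_excess(
      setNames(as.character(ages[single]), single),
      setNames(comp1, single),
      strategy = config$coloc_strategy,
      n_iter = config$coloc_iterations, seed = config$seed + 101L)
    reg <- tryCatch(
      excess_vs_branch_regression(
        setNames(coloc$mean_excess, coloc$branch)),
      error = function(e) NULL)
    pw_df <- read.delim(config$pathways, stringsAsFactors = FALSE)
    pathways <- split(pw_df$pathway_id, pw_df$protein_id)
    grouped <- intersect(names(ages), names(pathways))
    cof <- cofunction_expectation(
      pathways, setNames(as.character(ages[grouped]), grouped))
    write.table(coloc, file.path(outdir, "colocalization.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$pairs <- list(colocalization = coloc, regression = reg,
                      cofunction = cof)
    manifest$counts$pairs <- c(single_localized = length(single))
    .log_line("pairs: ", length(single), " single-localized proteins")
  }

  if ("diverge" %in% stages) {
    seqs <- read_fasta(config$fasta)
    seqs <- seqs[names(seqs) %in% names(called)]
    clusters <- greedy_cluster(seqs, config$cluster_identity,
                               config$cluster_word_length)
    filt <- filter_clusters(clusters, called,
                            min_clusters =
                              config$min_clusters_per_compartment)
    cd <- cluster_divergence(filt$clusters, seqs)
    cmp <- compare_compartment_divergence(cd)
    write.table(cmp$summary, file.path(outdir, "divergence_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$diverge <- list(clusters = clusters, filtered = filt,
                        divergence = cd, comparison = cmp)
    manifest$counts$diverge <- c(sequences = length(seqs),
                                 clusters_kept = nrow(filt$clusters),
                                 filt$attrition)
    .log_line("diverge: ", nrow(filt$clusters), " clusters kept (",
              paste(names(filt$attrition), filt$attrition, sep = "=",
                    collapse = " "), ")")
  }

  if ("ppi" %in% stages) {
    edges <- load_links(config$links, config$score_cutoff)
    edges <- edges[edges$protein_a %in% names(called) &
                     edges$protein_b %in% names(called), , drop = FALSE]
    dm <- density_matrix(edges, called)
    sims <- wc_bc_simulation(edges, called, n_sims = config$wc_bc_sims,
                             sample_size = config$wc_bc_sample,
                             seed = config$seed + 202L)
    write.table(dm$matrix, file.path(outdir, "density_matrix.tsv"),
                sep = "\t", quote = FALSE)
    res$ppi <- list(edges = edges, density = dm, simulation = sims)
    manifest$counts$ppi <- c(edges = nrow(edges),
                             deduped = attr(edges, "n_self_loops") %||% 0L)
    .log_line("ppi: ", nrow(edges), " edges after cutoff; WC/BC p = ",
              signif(sims$p_value, 3))
  }

  if ("paralogs" %in% stages) {
    raw_pairs <- read_paralog_table(config$paralogs)
    oriented <- orient_paralog_pairs(raw_pairs, ages)
    classified <- classify_pair_changes(oriented$pairs, called)
    spectrum <- pattern_spectrum(classified)
    seqs <- read_fasta(config$fasta)
    knk <- k_vs_nonk_comparison(classified, seqs)
    write.table(spectrum, file.path(outdir, "paralog_spectrum.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    res$paralogs <- list(oriented = oriented, classified = classified,
                         spectrum = spectrum, k_vs_nonk = knk)
    manifest$counts$paralogs <- c(pairs_in = nrow(raw_pairs),
                                  pairs_classified = nrow(classified),
                                  oriented$attrition)
    .log_line("paralogs: ", nrow(classified), " classified pairs")
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  res$manifest_path <- manifest_path
  invisible(res)
}
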